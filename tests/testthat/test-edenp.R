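test_that("the compiled system has the published membrane architecture", {
  img <- synth_image("vstep", 4)
  inst <- edenp_build(img, theta = 0.2)
  sys <- inst$system

  # 4-deep nest with membrane 4 as skin: 1 inside 2 inside 3 inside 4
  expect_identical(sys$skin, "4")
  expect_identical(sys$parents[match(c("1", "2", "3"), sys$labels)],
                   c("2", "3", "4"))

  # variable placement per membrane
  vm <- sys$var_membrane
  expect_true(all(vm[grep("^gx_|^gy_", names(vm))] == "1"))
  expect_true(all(vm[grep("^g_", names(vm))] == "2"))
  expect_true(all(vm[grep("^E_|^ED_|^ed[123]$", names(vm))] == "3"))
  expect_true(all(vm[grep("^x_|^edg_", names(vm))] == "4"))
  expect_identical(unname(vm[c("theta", "e1_1", "ED")]),
                   c("4", "4", "4"))

  # initial values: helper constants, seed enzyme, zeroed working variables
  v <- sys$initial_values
  expect_identical(unname(v[c("ed1", "ed2", "ed3", "e1_1", "ED")]),
                   c(0, 1, -256, 256, 0))
  expect_true(all(v[grep("^edg_|^gx_|^gy_|^g_|^E_|^ED_", names(v))] == 0))
})

test_that("instantiated resources match the closed-form variable counts", {
  for (n in c(4L, 8L)) {
    inst <- edenp_build(synth_image("checker", n), theta = 0.2)
    got <- edenp_instance_counts(inst)
    r <- edenp_resources(n)
    expect_identical(got$cells, r$cells)
    expect_identical(got$enzymatic_variables, r$enzymatic_variables)
    expect_identical(got$numerical_variables, r$numerical_variables)
    # the explicit rule families enumerate to 6n^2+1 (2n^2 gradient, n^2
    # magnitude, n^2 difference, 2n^2 decision, 1 halting)
    expect_identical(got$rules, 6L * n * n + 1L)
  }
  expect_identical(edenp_resources(16)$enzymatic_variables, 514L)
  expect_identical(edenp_resources(16)$numerical_variables, 1284L)
  expect_identical(edenp_resources(16)$molecules, 3338L)
  expect_identical(edenp_resources(16)$execution_steps, 5L)
  expect_identical(edenp_resources(3)$cells, 1L)
  expect_error(edenp_resources(2), ">= 3")
})

test_that("every border gradient variable gets exactly one zeroing rule", {
  n <- 5L
  inst <- edenp_build(synth_image("noise", n, seed = 2), theta = 0.2)
  zero_targets <- unlist(lapply(inst$system$programs, function(p)
    if (!is.na(p$group) && p$group == "gradient" &&
        identical(p$production, 0)) p$targets))
  border <- outer(1:n, 1:n, function(i, j)
    i == 1L | i == n | j == 1L | j == n)
  want <- c(sprintf("gx_%d_%d", row(border)[border], col(border)[border]),
            sprintf("gy_%d_%d", row(border)[border], col(border)[border]))
  expect_identical(sort(zero_targets), sort(want))
  expect_identical(anyDuplicated(zero_targets), 0L)
})

test_that("build rejects inputs the rules could not handle", {
  expect_error(edenp_build(synth_image("constant", 2)), "at least 3x3")
  expect_error(edenp_build(synth_image("vstep", 4), normalize = FALSE,
                           enzyme_seed = 100), "enzyme seed")
  expect_error(edenp_build(synth_image("vstep", 4), theta = -1),
               "non-negative")
  expect_error(edenp_build(synth_image("vstep", 4),
                           helper_constants = c(0, 1, 5)), "ed3 < ed1 < ed2")
})

test_that("the staged run takes 5 steps and fires the expected rule counts", {
  for (n in c(4L, 8L)) {
    inst <- edenp_build(synth_image("square", n, seed = 1), theta = 0.2)
    res <- edenp_execute(inst)
    expect_identical(res$steps, 5L)
    expect_true(res$run$halted)
    expect_identical(res$run$config$values[["ED"]], 1)
    # gradients, magnitudes, differences all fire once per pixel (x2 for
    # the two directions); decisions fire n^2 (always-on) + #edges times
    expect_identical(res$fired[1:3], c(2L * n * n, n * n, n * n))
    expect_identical(res$fired[4], n * n + sum(as_mat(res$edges)))
    expect_identical(res$fired[5], 1L)
  }
})

test_that("the membrane engine reproduces the serial oracle bit for bit", {
  cases <- list(
    list(kind = "vstep", n = 8, mask = "sobel", theta = 0.2),
    list(kind = "hstep", n = 9, mask = "prewitt", theta = 0.1),
    list(kind = "square", n = 8, mask = "roberts", theta = 0.2),
    list(kind = "noise", n = 12, mask = "sobel", theta = 0.5),
    list(kind = "ramp", n = 8, mask = "prewitt", theta = 0))
  for (cs in cases) {
    img <- synth_image(cs$kind, cs$n, seed = 42)
    got <- edenp_detect(img, theta = cs$theta, mask = cs$mask)
    want <- gbed(img, cs$mask, cs$theta)$edges
    expect_identical(as_mat(got), as_mat(want),
                     label = paste(cs$kind, cs$mask, cs$theta))
  }
  # normalization off: threshold interpreted on the raw 8-bit scale
  img <- synth_image("vstep", 6, seed = 1)
  got <- edenp_detect(img, theta = 51, normalize = FALSE)
  want <- gbed(img, "sobel", 51, normalize = FALSE)$edges
  expect_identical(as_mat(got), as_mat(want))
})

test_that("a vertical step lights up exactly the interior straddling columns", {
  n <- 8L
  img <- synth_image("vstep", n)  # step between columns 4 and 5
  got <- as_mat(edenp_detect(img, theta = 0.2, mask = "sobel"))
  want <- matrix(0L, n, n)
  want[2:(n - 1L), 4:5] <- 1L
  expect_identical(got, want)
})

test_that("theta = 0 marks every pixel, including zero-gradient borders", {
  img <- synth_image("constant", 5, bg = 128)
  got <- as_mat(edenp_detect(img, theta = 0))
  expect_true(all(got == 1L))
  # while any positive threshold clears a constant image completely
  expect_true(all(as_mat(edenp_detect(img, theta = 0.01)) == 0L))
})

test_that("edge sets shrink monotonically in the threshold", {
  img <- synth_image("disk", 10, seed = 9, noise_sd = 20)
  prev <- NULL
  for (theta in c(0, 0.1, 0.2, 0.5)) {
    e <- as_mat(edenp_detect(img, theta = theta))
    if (!is.null(prev)) expect_true(all(e <= prev))
    prev <- e
  }
})

test_that("borders are zeroed under the active anchoring convention", {
  img <- synth_image("noise", 7, seed = 13)
  for (mask in c("sobel", "prewitt")) {
    e <- as_mat(edenp_detect(img, theta = 0.2, mask = mask))
    expect_true(all(e[c(1, 7), ] == 0L) && all(e[, c(1, 7)] == 0L))
  }
  # Roberts masks anchor top-left: only the last row/column are zeroed
  er <- as_mat(edenp_detect(img, theta = 0.2, mask = "roberts"))
  expect_true(all(er[7, ] == 0L) && all(er[, 7] == 0L))
})

test_that("extraction demands a halted configuration and binary values", {
  img <- synth_image("vstep", 4)
  inst <- edenp_build(img)
  cfg <- enps_init(inst$system)
  expect_error(extract_edge_map(cfg, 4, 4), "not halted")
  res <- edenp_execute(inst)
  e <- extract_edge_map(res$run$config, 4, 4)
  expect_true(all(as_mat(e) %in% c(0L, 1L)))
})

test_that("rectangular images are supported", {
  img <- synth_image("vstep", 6, 10)
  got <- edenp_detect(img, theta = 0.2)
  want <- gbed(img, "sobel", 0.2)$edges
  expect_identical(as_mat(got), as_mat(want))
  expect_identical(dim(got), c(6L, 10L))
})

test_that("detect with verify cross-checks the engines in one call", {
  img <- synth_image("checker", 8, seed = 4)
  e <- edenp_detect(img, theta = 0.2, verify = TRUE)
  expect_identical(attr(e, "steps"), 5L)
  s <- edenp_detect(img, theta = 0.2, engine = "serial")
  expect_identical(as_mat(e), as_mat(s))
})
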