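# Independent reference implementations used as oracles. These deliberately
# re-derive the semantics with plain loops and share no code with the engine
# paths they check.

# brute-force one engine step: enumerate rules, test applicability, evaluate
# productions on the pre-step values, then reset-and-accumulate
brute_step <- function(system, values, consumption = "non-consuming") {
  fired <- list()
  for (p in system$programs) {
    applicable <- if (is.na(p$enzyme)) TRUE else {
      mn <- if (length(p$operands)) min(values[p$operands]) else 0
      if (p$comparison == "gt") values[[p$enzyme]] > mn
      else values[[p$enzyme]] >= mn
    }
    if (!applicable) next
    amount <- eval(p$production, as.list(values))
    fired[[length(fired) + 1L]] <- list(p = p, amount = amount)
  }
  new <- values
  if (length(fired)) {
    if (consumption == "consuming")
      for (f in fired) for (op in f$p$operands) new[[op]] <- 0
    for (f in fired) for (tg in f$p$targets) new[[tg]] <- 0
    for (f in fired) {
      cs <- sum(f$p$coefficients)
      inc <- if (cs == 0) rep(0, length(f$p$coefficients))
             else f$amount * f$p$coefficients / cs
      for (k in seq_along(f$p$targets))
        new[[f$p$targets[k]]] <- new[[f$p$targets[k]]] + inc[k]
    }
  }
  list(values = new, fired = length(fired))
}

# random one-membrane system with <= 8 variables and <= 5 rules; linear
# productions with integer coefficients, optional enzymes and mixed
# strict/non-strict comparisons
random_system <- function(seed) {
  set.seed(seed)
  nv <- sample(3:8, 1)
  vars <- paste0("v", seq_len(nv))
  vals <- round(stats::runif(nv, -5, 5), 2)
  nr <- sample(1:5, 1)
  enzymes_used <- character(0)
  programs <- vector("list", nr)
  for (k in seq_len(nr)) {
    n_ops <- sample(0:3, 1)
    ops <- if (n_ops) sample(vars, n_ops) else character(0)
    prod_str <- if (n_ops == 0) as.character(sample(-3:3, 1)) else
      paste(sprintf("%d * %s", sample(-3:3, n_ops, replace = TRUE), ops),
            collapse = " + ")
    targets <- sample(vars, sample(1:2, 1))
    pool <- setdiff(vars, c(ops, targets))
    enzyme <- if (length(pool) && stats::runif(1) < 0.6) sample(pool, 1)
              else NULL
    enzymes_used <- union(enzymes_used, enzyme)
    programs[[k]] <- enps_program(
      prod_str,
      stats::setNames(sample(1:3, length(targets), replace = TRUE), targets),
      membrane = "m", enzyme = enzyme,
      comparison = sample(c("ge", "gt"), 1),
      name = paste0("r", k))
  }
  enps_system(
    list(list(label = "m", parent = NA,
              variables = stats::setNames(vals, vars),
              enzymes = enzymes_used)),
    programs)
}

# naive per-pixel double-loop gradient-based edge detection; 3x3 masks are
# centered, 2x2 masks anchored top-left, out-of-window pixels give 0
naive_gbed <- function(m, mask_name, theta) {
  mp <- mask_pair(mask_name)
  h <- nrow(m); w <- ncol(m)
  k <- nrow(mp$mx)
  off <- if (k == 3L) -1L else 0L
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    r0 <- i + off; c0 <- j + off
    if (r0 < 1L || c0 < 1L || r0 + k - 1L > h || c0 + k - 1L > w) next
    sx <- 0; sy <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) {
      sx <- sx + mp$mx[a, b] * m[r0 + a - 1L, c0 + b - 1L]
      sy <- sy + mp$my[a, b] * m[r0 + a - 1L, c0 + b - 1L]
    }
    gx[i, j] <- sx; gy[i, j] <- sy
  }
  g <- sqrt(gx^2 + gy^2)
  list(gx = gx, gy = gy, g = g,
       edges = matrix(as.integer(g - theta >= 0), h, w))
}

# strip classes/attributes for raw matrix comparison
as_mat <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m))
  m
}
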