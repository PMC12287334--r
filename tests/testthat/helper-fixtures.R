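# Shared fixtures and independent oracles, built in code.

# A minimal two-variable linguistic configuration for engine-level tests:
# term supports are simple triangles/shoulders with a designed crossover at
# the domain midpoint (both adjacent terms at 0.5).
tiny_vars <- function() {
  mk <- function(name) {
    linguistic_variable(name, "-", c(0, 10), list(
      linguistic_term("Low", 1L,
        mf_spec("triangular", alpha_min = 0, beta = 0, alpha_max = 10)),
      linguistic_term("High", 2L,
        mf_spec("triangular", alpha_min = 0, beta = 10, alpha_max = 10))))
  }
  list(A = mk("A"), B = mk("B"))
}

tiny_rule_base <- function(rules) {
  rule_base(rules, variable_order = c("A", "B"), variables = tiny_vars())
}

# membership vector for the tiny configuration
tiny_mv <- function(a_low, a_high, b_low = 0, b_high = 0) {
  structure(list(A = c(Low = a_low, High = a_high),
                 B = c(Low = b_low, High = b_high)),
            class = "membership_vector")
}

# Independent centroid oracle: direct fine-grid integration of the
# clipped-and-aggregated output sets (delta = 0.001), no package internals.
centroid_oracle <- function(strengths_by_class, delta = 0.001) {
  out <- default_output_partition()
  x <- seq(0, 100, by = delta)
  env <- numeric(length(x))
  for (cl in out) {
    s <- strengths_by_class[cl$class_index]
    if (is.na(s) || s <= 0) next
    env <- pmax(env, pmin(mf_eval(cl$mf, x), s))
  }
  sum(x * env) / sum(env)
}

# Independent ordinary-kriging oracle in covariance (GLS) form:
#   mu_hat = (1' C^-1 z) / (1' C^-1 1)
#   pred   = mu_hat + c0' C^-1 (z - mu_hat)
# a formulation distinct from the production semivariance/Lagrange system.
ok_oracle <- function(points, model, target) {
  n <- nrow(points)
  D <- as.matrix(stats::dist(points[, c("x", "y")]))
  C <- model$sill - model_gamma(D, model)
  diag(C) <- model$sill
  d0 <- sqrt((points$x - target[1])^2 + (points$y - target[2])^2)
  c0 <- model$sill - model_gamma(d0, model)
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- as.numeric((t(one) %*% Ci %*% points$value) / (t(one) %*% Ci %*% one))
  as.numeric(mu + t(c0) %*% Ci %*% (points$value - mu))
}

# independent 8-connectivity component sizes via breadth-first flood fill
component_sizes <- function(codes) {
  nr <- nrow(codes); nc <- ncol(codes)
  seen <- matrix(FALSE, nr, nc)
  sizes <- integer(0)
  for (start in which(!is.na(codes))) {
    if (seen[start]) next
    cls <- codes[start]
    queue <- start
    seen[start] <- TRUE
    sz <- 0L
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      sz <- sz + 1L
      i <- ((cur - 1L) %% nr) + 1L
      j <- ((cur - 1L) %/% nr) + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1L || ii > nr || jj < 1L || jj > nc) next
        nxt <- (jj - 1L) * nr + ii
        if (!seen[nxt] && !is.na(codes[nxt]) && codes[nxt] == cls) {
          seen[nxt] <- TRUE
          queue <- c(queue, nxt)
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  sizes
}

# random valid mf_spec generator for property tests
random_mf <- function(family) {
  p <- sort(stats::runif(4, -10, 10))
  switch(family,
    triangular = mf_spec("triangular", alpha_min = p[1], beta = p[2],
                         alpha_max = p[4]),
    trapezoidal = mf_spec("trapezoidal", alpha_min = p[1], beta1 = p[2],
                          beta2 = p[3], alpha_max = p[4]),
    gaussian = mf_spec("gaussian", beta = p[2], alpha_g = stats::runif(1, 0.01, 5)),
    exponential_like = mf_spec("exponential_like", beta = p[2],
                               gamma = stats::runif(1, 0.01, 5)),
    s_shape = mf_spec("s_shape", alpha_min = p[1], alpha_max = p[4],
                      invert = stats::runif(1) < 0.5))
}

# one cached default synthetic study + scores for pipeline-level tests
study_cache <- new.env(parent = emptyenv())
default_study <- function(seed = 101L) {
  key <- paste0("s", seed)
  if (is.null(study_cache[[key]])) {
    st <- suppressWarnings(generate_soil_dataset(seed = seed))
    sc <- score_samples(st$samples)
    study_cache[[key]] <- list(study = st, scored = sc)
  }
  study_cache[[key]]
}
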