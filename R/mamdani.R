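#' Fertility class bands (0-100 score)
#'
#' Half-open bands, upper-closed only at 100:
#' Very low \[0,25), Low \[25,50), Moderate \[50,75), High \[75,90),
#' Very high \[90,100\].
#' @keywords internal
FERTILITY_BANDS <- data.frame(
  label = c("Very low", "Low", "Moderate", "High", "Very high"),
  lo = c(0, 25, 50, 75, 90),
  hi = c(25, 50, 75, 90, 100),
  stringsAsFactors = FALSE)

#' Default output partition on the 0-100 fertility score domain
#'
#' Four trapezoidal consequent sets centred on the published score bands,
#' one per rule consequent class: Unproductive -> Very low \[0,25\],
#' Low -> \[25,50\], Medium -> \[50,75\], Productive -> High \[75+\]. The
#' interior trapezoids are symmetric about their band midpoints (so a
#' clipped single-class envelope defuzzifies exactly to the midpoint);
#' supports overlap and jointly cover \[0, 100\]. The "Very high" band is a
#' classification band only — no rule consequent maps onto it.
#'
#' @return Object of class `output_partition`: list of
#'   `(label, class_index, mf)`.
#' @export
default_output_partition <- function() {
  mk <- function(label, idx, a, b1, b2, c)
    list(label = label, class_index = idx,
         mf = mf_spec("trapezoidal", alpha_min = a, beta1 = b1,
                      beta2 = b2, alpha_max = c))
  structure(list(
    mk("Very low", 1L, 0, 0, 20, 30),
    mk("Low", 2L, 20, 30, 45, 55),
    mk("Moderate", 3L, 45, 55, 70, 80),
    mk("High", 4L, 70, 80, 100, 100)),
    class = "output_partition")
}

validate_output_partition <- function(out) {
  idx <- vapply(out, `[[`, integer(1), "class_index")
  if (!setequal(idx, 1:4) || anyDuplicated(idx))
    stop("output partition must map class indices 1..4 uniquely", call. = FALSE)
  grid <- seq(0, 100, length.out = 512L)
  mx <- do.call(pmax, lapply(out, function(cl) mf_eval(cl$mf, grid)))
  if (any(mx <= 0))
    stop("output partition does not cover [0, 100]", call. = FALSE)
  invisible(out)
}

#' Mamdani inference
#'
#' Standard min-implication / max-aggregation: every rule's consequent set is
#' clipped at the rule's firing strength and the aggregated envelope is the
#' pointwise maximum of the clipped sets over a discretised \[0, 100\] grid.
#'
#' @param mv A `membership_vector` from [fuzzify()].
#' @param rb A `rule_base` (nonempty).
#' @param out An `output_partition` (default [default_output_partition()]).
#' @param delta Grid step of the output discretisation (default 0.1).
#' @return Object of class `aggregated_output`: list with `domain` (grid),
#'   `envelope` (membership per grid point) and `strengths` (per rule).
#' @export
infer <- function(mv, rb, out = default_output_partition(), delta = 0.1) {
  if (!length(rb$rules)) stop("empty rule base", call. = FALSE)
  stopifnot(delta > 0)
  validate_output_partition(out)
  grid <- seq(0, 100, by = delta)
  out_mf <- lapply(out, function(cl) mf_eval(cl$mf, grid))
  idx_of <- vapply(out, `[[`, integer(1), "class_index")
  strengths <- vapply(rb$rules, firing_strength, numeric(1),
                      mv = mv, variable_order = rb$variable_order)
  envelope <- numeric(length(grid))
  for (i in seq_along(rb$rules)) {
    if (strengths[i] <= 0) next
    k <- match(rb$rules[[i]]$consequent, idx_of)
    envelope <- pmax(envelope, pmin(out_mf[[k]], strengths[i]))
  }
  structure(list(domain = grid, envelope = envelope, strengths = strengths),
            class = "aggregated_output")
}

#' Centroid defuzzification
#'
#' Centre of mass of the aggregated envelope over its discretised domain:
#' \eqn{\sum x_i \mu_i / \sum \mu_i}. For an identically-zero envelope (no
#' rule covered the input) the domain midpoint 50 is returned and the result
#' carries the attribute `zero_activation = TRUE`, with a warning.
#'
#' @param agg An `aggregated_output` from [infer()].
#' @return Crisp score in \[0, 100\].
#' @export
defuzzify_centroid <- function(agg) {
  stopifnot(inherits(agg, "aggregated_output"))
  s <- sum(agg$envelope)
  if (s <= 0) {
    warning("all-zero envelope: no rule fired; returning domain midpoint 50",
            call. = FALSE)
    return(structure(50, zero_activation = TRUE))
  }
  sum(agg$domain * agg$envelope) / s
}

#' Classify a fertility score into its band
#'
#' Bands are half-open \[lo, hi) with the top band closed at 100:
#' Very low \[0,25), Low \[25,50), Moderate \[50,75), High \[75,90),
#' Very high \[90,100\].
#'
#' @param score Numeric vector of scores in \[0, 100\].
#' @return Factor of band labels.
#' @export
#' @examples
#' classify_score(c(17.4, 52.6, 25, 100))
classify_score <- function(score) {
  if (any(!is.finite(score) | score < 0 | score > 100))
    stop("score must lie in [0, 100]", call. = FALSE)
  i <- findInterval(score, FERTILITY_BANDS$lo)  # 100 falls into the top band
  factor(FERTILITY_BANDS$label[i], levels = FERTILITY_BANDS$label)
}

#' Score a batch of soil samples
#'
#' Fuzzifies, runs Mamdani inference and centroid defuzzification for every
#' sample. Deterministic: identical configuration and samples give
#' bit-identical output, independent of row order. Per-sample failures are
#' collected (score `NA`, message in the `error` column) without aborting
#' the batch.
#'
#' @param samples Data frame from [read_soil_samples()] (columns `id`, `x`,
#'   `y` plus one per variable).
#' @param variables Named list of `ling_variable`s.
#' @param rb A `rule_base`.
#' @param out An `output_partition`.
#' @param delta Output discretisation step.
#' @return Data frame with columns `id, x, y, fertility_score,
#'   fertility_class, zero_activation, error`.
#' @export
score_samples <- function(samples, variables = default_soil_variables(),
                          rb = default_rule_base(),
                          out = default_output_partition(), delta = 0.1) {
  n <- nrow(samples)
  score <- rep(NA_real_, n)
  zero <- logical(n)
  err <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      mv <- fuzzify(samples[i, , drop = FALSE], variables)
      agg <- infer(mv, rb, out, delta)
      withCallingHandlers(
        defuzzify_centroid(agg),
        warning = function(w) invokeRestart("muffleWarning"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      err[i] <- conditionMessage(res)
    } else {
      score[i] <- as.numeric(res)
      zero[i] <- isTRUE(attr(res, "zero_activation"))
    }
  }
  cls <- rep(NA_character_, n)
  ok <- !is.na(score)
  cls[ok] <- as.character(classify_score(score[ok]))
  data.frame(id = samples$id, x = samples$x, y = samples$y,
             fertility_score = score, fertility_class = cls,
             zero_activation = zero, error = err,
             stringsAsFactors = FALSE)
}

#' Write scored samples as delimited text
#'
#' Columns `id, x, y, fertility_score, fertility_class`.
#'
#' @param scored Data frame from [score_samples()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_scored_samples <- function(scored, path) {
  utils::write.csv(
    scored[, c("id", "x", "y", "fertility_score", "fertility_class")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
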