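#' Soil parameter names
#'
#' Canonical order of the twelve measured soil parameters. This order also
#' defines the antecedent slot positions of the rule base:
#' pH, OC (organic matter), EC, N, P, K, Fe, Mn, Zn, B, Cu, S.
#'
#' @name soil-parameters
#' @keywords internal
NULL

SOIL_VARIABLES <- c("pH", "EC", "OC", "N", "P", "K",
                    "S", "Fe", "Mn", "Zn", "B", "Cu")

# Antecedent slot order of the rule base (OM == OC).
RULE_SLOT_ORDER <- c("pH", "OC", "EC", "N", "P", "K",
                     "Fe", "Mn", "Zn", "B", "Cu", "S")

# CSV column -> variable name for the soil-sample table.
SAMPLE_COLUMNS <- c(ph = "pH", ec_dsm = "EC", oc_pct = "OC",
                    n_kgha = "N", p_kgha = "P", k_kgha = "K",
                    s_mgkg = "S", fe_mgkg = "Fe", mn_mgkg = "Mn",
                    zn_mgkg = "Zn", b_mgkg = "B", cu_mgkg = "Cu")

#' Construct a linguistic term
#'
#' @param label Term label (e.g. `"Low"`, `"Neutral"`).
#' @param level_index Integer level index (>= 1), the slot value used by the
#'   rule base antecedent encoding.
#' @param mf An [mf_spec()].
#' @return Object of class `ling_term`.
#' @export
linguistic_term <- function(label, level_index, mf) {
  stopifnot(is.character(label), nzchar(label), inherits(mf, "mf_spec"))
  level_index <- as.integer(level_index)
  stopifnot(length(level_index) == 1L, level_index >= 1L)
  structure(list(label = label, level_index = level_index, mf = mf),
            class = "ling_term")
}

#' Construct a linguistic variable
#'
#' A named input variable partitioned into ordered linguistic terms. Terms
#' are stored sorted by `level_index`; level indices must be unique and
#' labels nonempty. Coverage (every domain value holding positive membership
#' in at least one term) is checked on a fine grid.
#'
#' @param name Variable name (one of `pH, EC, OC, N, P, K, S, Fe, Mn, Zn, B, Cu`
#'   for the packaged defaults; arbitrary names are allowed).
#' @param units Unit string.
#' @param domain Numeric length-2 physical domain `c(lo, hi)`.
#' @param terms List of [linguistic_term()]s (at least 2).
#' @param check_coverage Verify positive membership across the domain.
#' @return Object of class `ling_variable`.
#' @export
linguistic_variable <- function(name, units, domain, terms, check_coverage = TRUE) {
  stopifnot(is.character(name), nzchar(name), length(domain) == 2L,
            domain[1] < domain[2], length(terms) >= 2L)
  lev <- vapply(terms, function(t) t$level_index, integer(1))
  if (anyDuplicated(lev))
    stop("duplicate level_index in variable '", name, "'", call. = FALSE)
  terms <- terms[order(lev)]
  v <- structure(list(name = name, units = units,
                      domain_lo = domain[1], domain_hi = domain[2],
                      terms = terms),
                 class = "ling_variable")
  if (check_coverage) {
    grid <- seq(domain[1], domain[2], length.out = 512L)
    mx <- do.call(pmax, lapply(terms, function(t) mf_eval(t$mf, grid)))
    if (any(mx <= 0))
      stop("variable '", name, "' has zero coverage at e.g. x = ",
           signif(grid[which(mx <= 0)[1]], 4), call. = FALSE)
  }
  v
}

#' @export
print.ling_variable <- function(x, ...) {
  cat("<ling_variable ", x$name, " [", x$domain_lo, ", ", x$domain_hi, "] ",
      x$units, ">\n", sep = "")
  for (t in x$terms)
    cat(sprintf("  %d %-18s %s\n", t$level_index, t$label, t$mf$family))
  invisible(x)
}

#' Read linguistic variables from a YAML configuration file
#'
#' The schema is a top-level `variables:` list; each entry carries `name`,
#' `units`, `domain: [lo, hi]` and a `terms:` list whose entries hold
#' `label`, `level`, `family` and the family's membership-function
#' parameters (see [mf_spec()]). The packaged default encodes all twelve
#' soil parameters.
#'
#' @param path YAML file; defaults to the packaged configuration.
#' @return Named list of [linguistic_variable()]s.
#' @export
read_soil_variables <- function(path = system.file("extdata", "soil_variables.yaml",
                                                   package = "fertzone")) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$variables)) stop("config has no 'variables' section", call. = FALSE)
  vars <- lapply(cfg$variables, function(v) {
    terms <- lapply(v$terms, function(t) {
      mf <- mf_spec(family = t$family,
                    alpha_min = t$alpha_min %||% NA_real_,
                    alpha_max = t$alpha_max %||% NA_real_,
                    beta = t$beta %||% NA_real_,
                    beta1 = t$beta1 %||% NA_real_,
                    beta2 = t$beta2 %||% NA_real_,
                    gamma = t$gamma %||% NA_real_,
                    alpha_g = t$alpha_g %||% NA_real_,
                    invert = isTRUE(t$invert))
      linguistic_term(t$label, t$level, mf)
    })
    linguistic_variable(v$name, v$units %||% "", as.numeric(v$domain), terms)
  })
  names(vars) <- vapply(vars, `[[`, character(1), "name")
  vars
}

#' Default linguistic variables for the twelve soil parameters
#'
#' Loads (and memoises) the packaged configuration.
#'
#' @return Named list of `ling_variable`s.
#' @export
default_soil_variables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_soil_variables()
    cache
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read soil samples from delimited text
#'
#' Expects a header with columns `id, x, y, ph, ec_dsm, oc_pct, n_kgha,
#' p_kgha, k_kgha, s_mgkg, fe_mgkg, mn_mgkg, zn_mgkg, b_mgkg, cu_mgkg`
#' (coordinates in projected metres). Values must be finite, non-negative,
#' and pH within \[0, 14\].
#'
#' @param path CSV file.
#' @return A `data.frame` with columns `id`, `x`, `y` and one column per
#'   soil parameter named by variable (`pH`, `EC`, ...).
#' @export
read_soil_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("id", "x", "y", names(SAMPLE_COLUMNS)), names(df))
  if (length(missing))
    stop("soil sample file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- data.frame(id = as.character(df$id), x = as.numeric(df$x),
                    y = as.numeric(df$y), stringsAsFactors = FALSE)
  for (col in names(SAMPLE_COLUMNS)) out[[SAMPLE_COLUMNS[[col]]]] <- as.numeric(df[[col]])
  validate_soil_samples(out)
  out
}

#' Write soil samples in the canonical CSV dialect
#'
#' @param samples Data frame as returned by [read_soil_samples()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_soil_samples <- function(samples, path) {
  out <- data.frame(id = samples$id, x = samples$x, y = samples$y)
  for (col in names(SAMPLE_COLUMNS)) out[[col]] <- samples[[SAMPLE_COLUMNS[[col]]]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_soil_samples <- function(samples) {
  for (v in SOIL_VARIABLES) {
    vals <- samples[[v]]
    if (is.null(vals)) stop("missing soil variable '", v, "'", call. = FALSE)
    bad <- !is.finite(vals)
    if (any(bad))
      stop("non-finite ", v, " value for sample id ",
           samples$id[which(bad)[1]], call. = FALSE)
    if (v == "pH" && any(vals < 0 | vals > 14))
      stop("pH outside [0, 14] for sample id ",
           samples$id[which(vals < 0 | vals > 14)[1]], call. = FALSE)
    if (v != "pH" && any(vals < 0))
      stop(v, " negative for sample id ", samples$id[which(vals < 0)[1]],
           call. = FALSE)
  }
  invisible(samples)
}

#' Fuzzify one soil sample
#'
#' Evaluates every term's membership function at the sample's measured
#' values, producing one degree per (variable, term). The result is a named
#' list: one numeric vector per variable, positions indexed by the term
#' `level_index` and named by the term label.
#'
#' @param sample A single-row data frame (or named list) holding one value
#'   per configured variable.
#' @param variables Named list of `ling_variable`s
#'   (default [default_soil_variables()]).
#' @return Object of class `membership_vector`.
#' @export
#' @examples
#' vars <- default_soil_variables()
#' s <- c(list(pH = 7, EC = 0.4, OC = 0.45, N = 120, P = 28, K = 135),
#'        list(S = 14, Fe = 3, Mn = 2.3, Zn = 0.85, B = 0.44, Cu = 0.5))
#' mv <- fuzzify(s, vars)
#' mv$pH
fuzzify <- function(sample, variables = default_soil_variables()) {
  degrees <- lapply(variables, function(v) {
    x <- sample[[v$name]]
    if (is.null(x) || length(x) != 1L || !is.finite(as.numeric(x)))
      stop("sample is missing a finite value for variable '", v$name, "'",
           call. = FALSE)
    x <- as.numeric(x)
    d <- numeric(max(vapply(v$terms, `[[`, integer(1), "level_index")))
    nm <- character(length(d))
    for (t in v$terms) {
      d[t$level_index] <- mf_eval(t$mf, x)
      nm[t$level_index] <- t$label
    }
    names(d) <- nm
    if (any(d < 0 | d > 1)) stop("membership degree outside [0,1] for '",
                                 v$name, "'", call. = FALSE)
    d
  })
  names(degrees) <- vapply(variables, `[[`, character(1), "name")
  structure(degrees, class = "membership_vector")
}

#' @export
print.membership_vector <- function(x, ...) {
  cat("<membership_vector over", length(x), "variables>\n")
  for (v in names(x)) {
    top <- which.max(x[[v]])
    cat(sprintf("  %-3s -> %s (%.3f)\n", v, names(x[[v]])[top], x[[v]][top]))
  }
  invisible(x)
}
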