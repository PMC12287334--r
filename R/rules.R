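#' Fertility consequent classes
#'
#' Index -> label mapping of the four rule consequents.
#' @keywords internal
CONSEQUENT_LABELS <- c("Unproductive", "Low", "Medium", "Productive")

#' Construct a fuzzy IF-THEN rule
#'
#' @param antecedent Integer vector, one slot per input variable in the rule
#'   base's `variable_order`; 0 marks an absent variable, `k >= 1` requires
#'   the term with `level_index == k`.
#' @param consequent Integer class index in 1..4
#'   (Unproductive, Low, Medium, Productive).
#' @param weight Rule weight in (0, 1\].
#' @param connection `"AND"` (min over clause degrees) or `"OR"` (max).
#' @param description Optional human-readable clause text.
#' @return Object of class `fuzzy_rule`.
#' @export
fuzzy_rule <- function(antecedent, consequent, weight = 1,
                       connection = c("AND", "OR"), description = NULL) {
  connection <- match.arg(connection)
  antecedent <- as.integer(antecedent)
  if (!length(antecedent) || all(antecedent == 0L))
    stop("rule needs at least one nonzero antecedent slot", call. = FALSE)
  if (any(antecedent < 0L))
    stop("antecedent slots must be >= 0", call. = FALSE)
  consequent <- as.integer(consequent)
  if (length(consequent) != 1L || consequent < 1L || consequent > 4L)
    stop("consequent must be in 1..4", call. = FALSE)
  if (!is.numeric(weight) || weight <= 0 || weight > 1)
    stop("weight must be in (0, 1]", call. = FALSE)
  structure(list(antecedent = antecedent, consequent = consequent,
                 weight = as.numeric(weight), connection = connection,
                 description = description),
            class = "fuzzy_rule")
}

#' Construct a rule base
#'
#' @param rules List of [fuzzy_rule()]s, all with the same antecedent length.
#' @param variable_order Character vector naming the antecedent slots, in
#'   order. Defaults to the canonical 12-slot order
#'   `pH, OC, EC, N, P, K, Fe, Mn, Zn, B, Cu, S` ("OM" in rule text is the
#'   organic-carbon variable `OC`).
#' @param variables Named list of `ling_variable`s used to validate that
#'   every nonzero slot value is a valid level index.
#' @return Object of class `rule_base`.
#' @export
rule_base <- function(rules, variable_order = RULE_SLOT_ORDER,
                      variables = default_soil_variables()) {
  stopifnot(is.list(rules))
  nslot <- length(variable_order)
  for (r in rules) {
    stopifnot(inherits(r, "fuzzy_rule"))
    if (length(r$antecedent) != nslot)
      stop("rule antecedent length ", length(r$antecedent),
           " != |variable_order| = ", nslot, call. = FALSE)
  }
  # validate level indices against the variable definitions
  for (r in rules) {
    nz <- which(r$antecedent != 0L)
    for (j in nz) {
      vn <- variable_order[j]
      v <- variables[[vn]]
      if (is.null(v)) next
      levs <- vapply(v$terms, `[[`, integer(1), "level_index")
      if (!(r$antecedent[j] %in% levs))
        stop("rule uses level ", r$antecedent[j], " for variable '", vn,
             "' but defined levels are {", paste(levs, collapse = ","), "}",
             call. = FALSE)
    }
  }
  key <- vapply(rules, function(r)
    paste(c(r$antecedent, r$consequent), collapse = ","), character(1))
  if (anyDuplicated(key))
    stop("duplicate (antecedent, consequent) pair at rule ",
         which(duplicated(key))[1], call. = FALSE)
  structure(list(rules = rules, variable_order = variable_order),
            class = "rule_base")
}

#' @export
print.rule_base <- function(x, ...) {
  cat("<rule_base:", length(x$rules), "rules over",
      length(x$variable_order), "variables>\n")
  invisible(x)
}

#' @export
length.rule_base <- function(x) length(x$rules)

#' Parse a rule file
#'
#' Two documented forms are accepted and round-trip to identical rules:
#'
#' * **vector form** — delimited text (CSV) with columns `antecedent`
#'   (semicolon-separated integers, one per slot of `variable_order`),
#'   `consequent` (1-4), `weight`, `connection` (`AND`|`OR`) and an optional
#'   `description`.
#' * **clause form** — one rule per line,
#'   `IF <var> is <Term> [AND|OR <var> is <Term>]... THEN fertility is <Class>`,
#'   where `<Class>` is `Unproductive`, `Low`, `Medium` or `Productive`
#'   (`Poor` and `Moderate` are accepted as synonyms of `Low` and `Medium`,
#'   `High` of `Productive`). A trailing `[weight]`, e.g. `[0.8]`, sets the
#'   rule weight. `OM` is accepted as a synonym for `OC`.
#'
#' @param path Rule file. Format is detected from the header line.
#' @param variables Named list of `ling_variable`s for label resolution.
#' @param variable_order Antecedent slot order.
#' @return A [rule_base()].
#' @export
parse_rules <- function(path, variables = default_soil_variables(),
                        variable_order = RULE_SLOT_ORDER) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(structure(list(rules = list(), variable_order = variable_order),
                     class = "rule_base"))
  if (grepl("antecedent", lines[1], ignore.case = TRUE))
    parse_rules_vector(path, variables, variable_order)
  else
    parse_rules_clauses(lines, variables, variable_order)
}

parse_rules_vector <- function(path, variables, variable_order) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("antecedent", "consequent", "weight", "connection")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("rule file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rules <- lapply(seq_len(nrow(df)), function(i) {
    ant <- suppressWarnings(as.integer(strsplit(df$antecedent[i], ";")[[1]]))
    if (anyNA(ant))
      stop("line ", i + 1L, ": malformed antecedent vector", call. = FALSE)
    cons <- df$consequent[i]
    if (is.na(cons) || cons < 1 || cons > 4)
      stop("line ", i + 1L, ": consequent outside 1..4", call. = FALSE)
    fuzzy_rule(ant, cons, df$weight[i], toupper(df$connection[i]),
               description = if ("description" %in% names(df)) df$description[i])
  })
  rule_base(rules, variable_order, variables)
}

CONSEQUENT_SYNONYMS <- c(Unproductive = 1L, Poor = 2L, Low = 2L,
                         Moderate = 3L, Medium = 3L,
                         High = 4L, Productive = 4L)

parse_rules_clauses <- function(lines, variables, variable_order) {
  rules <- lapply(seq_along(lines), function(i) {
    ln <- trimws(lines[i])
    weight <- 1
    wm <- regmatches(ln, regexec("\\[([0-9.]+)\\]\\s*$", ln))[[1]]
    if (length(wm)) {
      weight <- as.numeric(wm[2])
      ln <- trimws(sub("\\[[0-9.]+\\]\\s*$", "", ln))
    }
    m <- regexec("^IF\\s+(.*)\\s+THEN\\s+fertility\\s+is\\s+(\\S+)\\s*$", ln,
                 ignore.case = TRUE)
    parts <- regmatches(ln, m)[[1]]
    if (length(parts) != 3L)
      stop("line ", i, ": cannot parse clause rule", call. = FALSE)
    cons <- CONSEQUENT_SYNONYMS[[parts[3]]]
    if (is.null(cons))
      stop("line ", i, ": unknown consequent label '", parts[3], "'",
           call. = FALSE)
    body <- parts[2]
    has_or <- grepl("\\bOR\\b", body)
    has_and <- grepl("\\bAND\\b", body)
    if (has_or && has_and)
      stop("line ", i, ": mixed AND/OR connectives are not supported",
           call. = FALSE)
    connective <- if (has_or) "OR" else "AND"
    clauses <- strsplit(body, "\\s+(AND|OR)\\s+")[[1]]
    ant <- integer(length(variable_order))
    for (cl in clauses) {
      cm <- regmatches(cl, regexec("^(\\S+)\\s+is\\s+(\\S+)$", cl,
                                   ignore.case = TRUE))[[1]]
      if (length(cm) != 3L)
        stop("line ", i, ": cannot parse clause '", cl, "'", call. = FALSE)
      vn <- cm[2]
      if (toupper(vn) == "OM") vn <- "OC"
      slot <- match(vn, variable_order)
      if (is.na(slot))
        stop("line ", i, ": unknown variable '", cm[2], "'", call. = FALSE)
      v <- variables[[vn]]
      labels <- vapply(v$terms, `[[`, character(1), "label")
      ti <- match(cm[3], labels)
      if (is.na(ti))
        stop("line ", i, ": unknown term '", cm[3], "' for variable '",
             vn, "'", call. = FALSE)
      ant[slot] <- v$terms[[ti]]$level_index
    }
    fuzzy_rule(ant, cons, weight, connective, description = ln)
  })
  rule_base(rules, variable_order, variables)
}

#' Render rules in clause form
#'
#' Inverse of the clause parser: every rule becomes one
#' `IF ... THEN fertility is ...` line. `parse_rules()` on the result
#' reconstructs an identical rule base (round-trip property).
#'
#' @param rb A `rule_base`.
#' @param variables Named list of `ling_variable`s for term labels.
#' @return Character vector, one clause line per rule.
#' @export
rules_to_clauses <- function(rb, variables = default_soil_variables()) {
  vapply(rb$rules, function(r) {
    nz <- which(r$antecedent != 0L)
    clauses <- vapply(nz, function(j) {
      vn <- rb$variable_order[j]
      v <- variables[[vn]]
      levs <- vapply(v$terms, `[[`, integer(1), "level_index")
      lab <- v$terms[[match(r$antecedent[j], levs)]]$label
      paste(vn, "is", lab)
    }, character(1))
    line <- paste0("IF ", paste(clauses, collapse = paste0(" ", r$connection, " ")),
                   " THEN fertility is ", CONSEQUENT_LABELS[r$consequent])
    if (r$weight != 1) line <- paste0(line, " [", format(r$weight), "]")
    line
  }, character(1))
}

#' Default expert rule base
#'
#' The 25 unique rules reconstructed from the published rule tables (the two
#' tables share one rule, so 26 printed rows give 25 distinct
#' antecedent/consequent pairs). Users supply their own file via
#' [parse_rules()] to extend the base towards the full 80-rule expert set,
#' which was never published.
#'
#' @return A `rule_base`.
#' @export
default_rule_base <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- parse_rules(system.file("extdata", "default_rules.csv",
                                        package = "fertzone"))
    cache
  }
})

#' Firing strength of one rule
#'
#' `weight * min` over the referenced term degrees for AND rules,
#' `weight * max` for OR rules.
#'
#' @param rule A `fuzzy_rule`.
#' @param mv A `membership_vector` from [fuzzify()].
#' @param variable_order Slot order naming the antecedent positions.
#' @return Firing strength in \[0, 1\].
#' @export
firing_strength <- function(rule, mv, variable_order = RULE_SLOT_ORDER) {
  nz <- which(rule$antecedent != 0L)
  degs <- vapply(nz, function(j) {
    vn <- variable_order[j]
    d <- mv[[vn]]
    if (is.null(d))
      stop("membership vector has no degrees for variable '", vn, "'",
           call. = FALSE)
    k <- rule$antecedent[j]
    if (k > length(d))
      stop("no term with level ", k, " for variable '", vn, "'", call. = FALSE)
    d[[k]]
  }, numeric(1))
  rule$weight * if (rule$connection == "OR") max(degs) else min(degs)
}

#' Size of the combinatorial rule space
#'
#' Number of distinct complete antecedent assignments:
#' `n_levels ^ n_criteria`, computed in exact integer arithmetic (the result
#' is returned as double when it exceeds `.Machine$integer.max`).
#'
#' @param n_levels Number of linguistic levels per criterion (>= 1).
#' @param n_criteria Number of criteria (>= 1).
#' @return The exact count.
#' @export
#' @examples
#' rule_space_size(3, 12)  # 531441
rule_space_size <- function(n_levels, n_criteria) {
  if (!is.numeric(n_levels) || !is.numeric(n_criteria) ||
      n_levels < 1 || n_criteria < 1 ||
      n_levels != round(n_levels) || n_criteria != round(n_criteria))
    stop("n_levels and n_criteria must be positive integers", call. = FALSE)
  out <- 1
  for (i in seq_len(n_criteria)) out <- out * n_levels
  out
}
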