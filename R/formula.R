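#' @importFrom methods as is new
#' @importFrom stats coef fft median na.omit quantile rnorm runif sd var
#' @importFrom utils read.csv write.csv head tail
NULL

# ---------------------------------------------------------------------------
# Wilkinson-notation model terms
#
# Supported grammar (left-hand side accepted and ignored):
#   y ~ [1|0] {+|*|:} term ...
#   term := 1 | name | cat(name) | spl(name, n) | 2dspl(a, b, n)
#           | circspl(name, n, lo, hi)
# `a*b` expands to a + b + a:b; `a:b` yields only the interaction.
# Spline-type terms may not take part in * or : (non-linear interactions go
# through 2dspl instead).
# ---------------------------------------------------------------------------

new_term <- function(kind, variables = character(), n_basis = NULL,
                     cycle_bounds = NULL, coding = NULL) {
  t <- list(kind = kind, variables = variables, n_basis = n_basis,
            cycle_bounds = cycle_bounds, coding = coding)
  class(t) <- "erp_term"
  t
}

#' @export
format.erp_term <- function(x, ...) render_term(x)

#' @export
print.erp_term <- function(x, ...) {
  cat("<term> ", render_term(x), "\n", sep = "")
  invisible(x)
}

term_label <- function(term) render_term(term)

#' Render a parsed term back to canonical formula text
#'
#' @param term an `erp_term` as returned by [parse_formula()].
#' @return a single string in the formula syntax.
#' @keywords internal
render_term <- function(term) {
  switch(term$kind,
    intercept   = "1",
    continuous  = term$variables,
    categorical = sprintf("cat(%s)", term$variables),
    spline      = sprintf("spl(%s,%d)", term$variables, term$n_basis),
    spline2d    = sprintf("2dspl(%s,%s,%d)", term$variables[1],
                          term$variables[2], term$n_basis),
    circspline  = sprintf("circspl(%s,%d,%s,%s)", term$variables,
                          term$n_basis, format(term$cycle_bounds[1]),
                          format(term$cycle_bounds[2])),
    interaction = paste(vapply(term$parents, render_term, ""), collapse = ":"),
    stop("unknown term kind: ", term$kind)
  )
}

#' Render a term list to a canonical formula string
#'
#' @param terms list of `erp_term`s.
#' @param lhs left-hand-side symbol to print.
#' @return formula text whose parse equals `terms`.
#' @export
render_formula <- function(terms, lhs = "y") {
  has_int <- any(vapply(terms, function(t) t$kind == "intercept", TRUE))
  rhs <- vapply(terms, render_term, "")
  if (!has_int) rhs <- c("0", rhs)
  paste(lhs, "~", paste(rhs, collapse = " + "))
}

# split `s` on single-char operators in `ops` at parenthesis depth 0;
# returns data.frame(piece, start) with 1-based start offsets into `s`
split_top <- function(s, ops) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  cuts <- integer()
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop(sprintf("parse error at position %d: unbalanced ')'", i))
    } else if (depth == 0L && ch %in% ops) cuts <- c(cuts, i)
  }
  if (depth != 0L) stop("parse error: unbalanced '(' in formula")
  starts <- c(1L, cuts + 1L)
  stops <- c(cuts - 1L, length(chars))
  data.frame(
    piece = vapply(seq_along(starts), function(k)
      paste(chars[seq.int(starts[k], length.out = max(0L, stops[k] - starts[k] + 1L))],
            collapse = ""), ""),
    start = starts,
    op = c("", chars[cuts]),
    stringsAsFactors = FALSE
  )
}

parse_atom <- function(text, pos) {
  s <- trimws(text)
  if (s == "")
    stop(sprintf("parse error at position %d: empty term", pos))
  if (s == "1") return(new_term("intercept"))
  if (s == "0") return(new_term("nointercept"))
  m <- regmatches(s, regexec("^([A-Za-z0-9_.]+)\\s*\\((.*)\\)$", s))[[1]]
  if (length(m) == 0) {
    if (!grepl("^[A-Za-z.][A-Za-z0-9_.]*$", s))
      stop(sprintf("parse error at position %d: invalid term '%s'", pos, s))
    return(new_term("continuous", s))
  }
  fun <- m[2]
  args <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
  bad_arity <- function(want)
    stop(sprintf("parse error at position %d: %s() expects %s argument(s), got %d",
                 pos, fun, want, length(args)))
  num <- function(a, what) {
    v <- suppressWarnings(as.numeric(a))
    if (is.na(v)) stop(sprintf(
      "parse error at position %d: %s of %s() must be numeric, got '%s'",
      pos, what, fun, a))
    v
  }
  switch(fun,
    cat = {
      if (length(args) != 1) bad_arity("1")
      new_term("categorical", args[1], coding = "treatment")
    },
    spl = {
      if (length(args) != 2) bad_arity("2")
      nb <- as.integer(num(args[2], "n_basis"))
      if (nb < 2) stop(sprintf(
        "parse error at position %d: spl() needs n_basis >= 2", pos))
      new_term("spline", args[1], n_basis = nb)
    },
    `2dspl` = {
      if (length(args) != 3) bad_arity("3")
      if (args[1] == args[2]) stop(sprintf(
        "parse error at position %d: 2dspl() variables must be distinct", pos))
      nb <- as.integer(num(args[3], "n_basis"))
      if (nb < 2) stop(sprintf(
        "parse error at position %d: 2dspl() needs n_basis >= 2", pos))
      new_term("spline2d", c(args[1], args[2]), n_basis = nb)
    },
    circspl = {
      if (length(args) != 4) bad_arity("4")
      nb <- as.integer(num(args[2], "n_basis"))
      lo <- num(args[3], "lower bound")
      hi <- num(args[4], "upper bound")
      if (nb < 2) stop(sprintf(
        "parse error at position %d: circspl() needs n_basis >= 2", pos))
      if (!(lo < hi)) stop(sprintf(
        "parse error at position %d: circspl() bounds must satisfy lo < hi", pos))
      new_term("circspline", args[1], n_basis = nb, cycle_bounds = c(lo, hi))
    },
    stop(sprintf("parse error at position %d: unknown term function '%s'",
                 pos, fun))
  )
}

is_spline_kind <- function(term)
  term$kind %in% c("spline", "spline2d", "circspline")

make_interaction <- function(parents, pos) {
  if (any(vapply(parents, is_spline_kind, TRUE)))
    stop(sprintf(paste0(
      "unsupported interaction at position %d: spline-type terms cannot ",
      "appear in '*' or ':' (use 2dspl() for non-linear interactions)"), pos))
  if (any(vapply(parents, function(p) p$kind == "intercept", TRUE)))
    stop(sprintf("parse error at position %d: '1' cannot enter an interaction",
                 pos))
  vars <- unlist(lapply(parents, `[[`, "variables"))
  if (anyDuplicated(vars))
    stop(sprintf("parse error at position %d: interaction variables must be distinct",
                 pos))
  t <- new_term("interaction", vars)
  t$parents <- parents
  t
}

#' Parse a Wilkinson-notation model formula
#'
#' Parses formula text of the form `y ~ 1 + cat(cond) + lum + spl(x, 5) +
#' 2dspl(a, b, 5) + circspl(ang, 5, 0, 360)` into a list of typed terms.
#' The left-hand side is accepted and ignored (the response is always the
#' recorded data). An intercept is included implicitly unless the right-hand
#' side starts with `0`. `a*b` expands to `a + b + a:b`; `a:b` yields only
#' the interaction. Interactions are supported between categorical and/or
#' plain continuous predictors only; non-linear interactions are expressed
#' with `2dspl()`.
#'
#' @param text formula string.
#' @return list of `erp_term` objects in left-to-right order.
#' @examples
#' parse_formula("y ~ 1 + cat(is_face) + luminance")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  tilde <- regexpr("~", text, fixed = TRUE)
  if (tilde < 0) stop("parse error: formula must contain '~'")
  rhs <- substr(text, tilde + 1L, nchar(text))
  rhs_off <- tilde
  sums <- split_top(rhs, "+")
  terms <- list()
  saw_nointercept <- FALSE
  explicit_intercept <- FALSE
  for (k in seq_len(nrow(sums))) {
    pos <- rhs_off + sums$start[k]
    prods <- split_top(sums$piece[k], c("*", ":"))
    atoms <- lapply(seq_len(nrow(prods)), function(j)
      parse_atom(prods$piece[j], rhs_off + sums$start[k] + prods$start[j] - 1L))
    if (nrow(prods) == 1) {
      a <- atoms[[1]]
      if (a$kind == "nointercept") {
        if (k != 1) stop(sprintf(
          "parse error at position %d: '0' only allowed as leading term", pos))
        saw_nointercept <- TRUE
        next
      }
      if (a$kind == "intercept") { explicit_intercept <- TRUE; next }
      terms <- c(terms, list(a))
    } else {
      ops <- prods$op[-1]
      if (any(vapply(atoms, function(a)
        a$kind %in% c("intercept", "nointercept"), TRUE)))
        stop(sprintf("parse error at position %d: '0'/'1' cannot enter '*' or ':'",
                     pos))
      if (length(atoms) != 2)
        stop(sprintf("parse error at position %d: only pairwise '*'/'%s' supported",
                     pos, ":"))
      if (all(ops == "*")) {
        terms <- c(terms, atoms, list(make_interaction(atoms, pos)))
      } else if (all(ops == ":")) {
        terms <- c(terms, list(make_interaction(atoms, pos)))
      } else {
        stop(sprintf("parse error at position %d: mixing '*' and ':' unsupported",
                     pos))
      }
    }
  }
  if (saw_nointercept && explicit_intercept)
    stop("parse error: formula contains both '0' and '1'")
  if (!saw_nointercept)
    terms <- c(list(new_term("intercept")), terms)
  labels <- vapply(terms, term_label, "")
  if (anyDuplicated(labels))
    stop("duplicate term in formula: ", labels[duplicated(labels)][1])
  # reject cat() and a spline kind wrapping the same predictor: ambiguous
  catvars <- unlist(lapply(terms, function(t)
    if (t$kind == "categorical") t$variables else NULL))
  splvars <- unlist(lapply(terms, function(t)
    if (is_spline_kind(t)) t$variables else NULL))
  clash <- intersect(catvars, splvars)
  if (length(clash))
    stop("conflicting term types for predictor '", clash[1],
         "': cat() and spline terms cannot share a predictor")
  terms
}

# ---------------------------------------------------------------------------
# ModelSpec
# ---------------------------------------------------------------------------

#' Define a per-event-type model
#'
#' Bundles the Wilkinson formula, the estimation window (in seconds relative
#' to event onset), the temporal basis used in time expansion, and optional
#' categorical reference levels for one event type.
#'
#' @param event_type event type string matched against the event table's
#'   `type` column.
#' @param formula formula text (see [parse_formula()]).
#' @param window numeric length-2, `c(tau_min, tau_max)` seconds,
#'   `tau_min < tau_max`.
#' @param basis a temporal basis from [temporal_basis()]; default stick
#'   (FIR) functions.
#' @param ref_levels optional named character vector mapping categorical
#'   predictor name to its reference level (default: alphabetically first).
#' @param coding `"treatment"` (default) or `"effects"` coding for
#'   categorical predictors.
#' @return an object of class `erp_model_spec`.
#' @export
model_spec <- function(event_type, formula, window,
                       basis = temporal_basis("stick"),
                       ref_levels = NULL, coding = c("treatment", "effects")) {
  coding <- match.arg(coding)
  stopifnot(is.numeric(window), length(window) == 2)
  if (!(window[1] < window[2]))
    stop("window must satisfy tau_min < tau_max")
  terms <- parse_formula(formula)
  for (i in seq_along(terms))
    if (terms[[i]]$kind == "categorical") terms[[i]]$coding <- coding
  structure(list(event_type = event_type, formula = formula, terms = terms,
                 window = window, basis = basis, ref_levels = ref_levels,
                 coding = coding),
            class = "erp_model_spec")
}

#' @export
print.erp_model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> '%s': %s  window [%g, %g] s, basis %s\n",
              x$event_type, render_formula(x$terms), x$window[1], x$window[2],
              x$basis$kind))
  invisible(x)
}

#' Validate a model spec against an event table
#'
#' Checks that every referenced predictor exists for the spec's event type,
#' categorical predictors have at least two observed levels, and spline
#' predictors are numeric. Diagnostics are returned, not raised.
#'
#' @param spec an `erp_model_spec`.
#' @param events event table data.frame (see [read_events()]).
#' @return character vector of human-readable diagnostics; empty when valid.
#' @export
validate_spec <- function(spec, events) {
  stopifnot(inherits(spec, "erp_model_spec"), is.data.frame(events))
  ev <- events[events$type == spec$event_type, , drop = FALSE]
  out <- character()
  if (nrow(ev) == 0)
    out <- c(out, sprintf("no events of type '%s' in event table",
                          spec$event_type))
  check_term <- function(t) {
    if (t$kind %in% c("intercept", "nointercept")) return(character())
    if (t$kind == "interaction")
      return(unlist(lapply(t$parents, check_term)))
    unlist(lapply(t$variables, function(v) {
      if (!v %in% names(events))
        return(sprintf("predictor '%s' not found in event table", v))
      col <- ev[[v]]
      if (t$kind == "categorical") {
        if (length(unique(na.omit(col))) < 2)
          return(sprintf("categorical predictor '%s' has fewer than 2 levels",
                         v))
      } else if (!is.numeric(col)) {
        return(sprintf("predictor '%s' must be numeric for a %s term", v,
                       t$kind))
      }
      character()
    }))
  }
  unique(c(out, unlist(lapply(spec$terms, check_term))))
}
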