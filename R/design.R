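# ---------------------------------------------------------------------------
# Event tables and instance-level design matrices
# ---------------------------------------------------------------------------

#' Read an event table
#'
#' Reads a BIDS-events-style delimited file with a header row and at least
#' the columns `onset` (seconds) and `type`; all further columns are treated
#' as predictors. Missing values may be encoded as empty fields or `NaN`.
#' Rows are sorted by onset; the original row order is retained in column
#' `.orig_index`.
#'
#' @param path file path; tab- or comma-separated (inferred from the
#'   extension: `.tsv` tab, otherwise comma).
#' @param duration optional recording duration in seconds; onsets at or
#'   beyond it are rejected.
#' @return a data.frame event table.
#' @export
read_events <- function(path, duration = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  ev <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "NaN", "n/a"))
  as_event_table(ev, duration = duration)
}

#' Validate and normalize an event table
#'
#' @param events data.frame with columns `onset` (seconds) and `type`.
#' @param duration optional recording duration in seconds.
#' @return the table sorted by onset, with `.orig_index` added.
#' @export
as_event_table <- function(events, duration = NULL) {
  stopifnot(is.data.frame(events))
  if (!all(c("onset", "type") %in% names(events)))
    stop("event table must have columns 'onset' and 'type'")
  if (any(!is.finite(events$onset)))
    stop("event onsets must be finite")
  if (any(events$onset < 0))
    stop("event onsets must be >= 0")
  if (!is.null(duration) && any(events$onset >= duration))
    stop("event onsets must lie within the recording duration")
  if (is.null(events$.orig_index)) events$.orig_index <- seq_len(nrow(events))
  events[order(events$onset), , drop = FALSE]
}

#' Impute missing predictor values
#'
#' Treats `NA`/`NaN` entries in predictor columns, separately within each
#' event type. `drop` removes the whole event instance (with a warning: a
#' dropped event's overlapping activity is no longer accounted for).
#' `mean`/`median` replace missing entries by the column statistic over the
#' non-missing rows of the same event type. `marginal` replaces each missing
#' entry by a uniform random draw from the observed non-missing values of
#' that column (seeded, reproducible).
#'
#' @param events event table.
#' @param method one of `"drop"`, `"mean"`, `"median"`, `"marginal"`.
#' @param seed integer seed, required for `method = "marginal"`.
#' @return the imputed event table.
#' @export
impute_missing <- function(events, method = c("drop", "mean", "median",
                                              "marginal"), seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(events))
  pred_cols <- setdiff(names(events), c("onset", "type", ".orig_index"))
  if (method == "drop") {
    bad <- rowSums(is.na(events[, pred_cols, drop = FALSE])) > 0
    if (any(bad))
      warning(sum(bad), " event(s) dropped; their overlap contribution is ",
              "no longer modeled")
    return(events[!bad, , drop = FALSE])
  }
  if (method == "marginal") {
    if (is.null(seed)) stop("marginal imputation requires a seed")
    rng <- local_rng(seed)
    on.exit(rng(), add = TRUE)
  }
  for (tp in unique(events$type)) {
    idx <- which(events$type == tp)
    for (cl in pred_cols) {
      col <- events[[cl]][idx]
      miss <- is.na(col)
      if (!any(miss)) next
      obs <- col[!miss]
      if (length(obs) == 0)
        stop("column '", cl, "' has no observed values for event type '",
             tp, "': cannot impute")
      rep_val <- switch(method,
        mean = mean(obs),
        median = median(obs),
        marginal = obs[sample.int(length(obs), sum(miss), replace = TRUE)]
      )
      events[[cl]][idx[miss]] <- rep_val
    }
  }
  events
}

# run code under a private RNG stream; returns a restore function
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

# alphabetical (locale-independent) level ordering with optional reference
# level moved first
order_levels <- function(values, ref = NULL) {
  lev <- sort(unique(as.character(values)), method = "radix")
  if (!is.null(ref)) {
    if (!ref %in% lev) stop("reference level '", ref, "' not observed")
    lev <- c(ref, setdiff(lev, ref))
  }
  lev
}

# coded columns for one term; returns list(values, labels, basis_index, meta)
code_term <- function(term, ev, ref_levels, has_intercept) {
  n <- nrow(ev)
  lab <- term_label(term)
  switch(term$kind,
    intercept = list(values = matrix(1, n, 1), labels = "(Intercept)",
                     basis_index = NA_integer_, meta = NULL),
    continuous = list(values = matrix(ev[[term$variables]], n, 1),
                      labels = lab, basis_index = NA_integer_, meta = NULL),
    categorical = {
      v <- term$variables
      lev <- order_levels(ev[[v]], ref_levels[[v]])
      L <- length(lev)
      if (L < 2) stop("categorical predictor '", v, "' has < 2 levels")
      x <- as.character(ev[[v]])
      if (identical(term$coding, "effects")) {
        # sum-to-zero: indicator for each of the first L-1 levels, the
        # (alphabetically) last level coded -1 throughout
        cols <- vapply(lev[-L], function(l)
          ifelse(x == l, 1, ifelse(x == lev[L], -1, 0)), numeric(n))
        labels <- paste0(v, ".", lev[-L])
      } else {
        cols <- vapply(lev[-1], function(l) as.numeric(x == l), numeric(n))
        labels <- paste0(v, ".", lev[-1])
      }
      list(values = matrix(cols, n), labels = labels,
           basis_index = seq_len(L - 1L),
           meta = list(levels = lev, coding = term$coding))
    },
    spline = {
      v <- term$variables
      knots <- quantile_knots(ev[[v]], term$n_basis)
      B <- bspline_basis(ev[[v]], knots)
      drop_idx <- NA_integer_; ref_x <- NA_real_
      if (has_intercept) {
        peaks <- bspline_peaks(knots)
        drop_idx <- which.min(abs(peaks - median(ev[[v]])))
        ref_x <- peaks[drop_idx]
        B <- B[, -drop_idx, drop = FALSE]
      }
      keep <- setdiff(seq_len(term$n_basis), drop_idx)
      list(values = B, labels = paste0(v, ".spl", keep), basis_index = keep,
           meta = list(knots = knots, dropped = drop_idx, ref_x = ref_x,
                       n_basis = term$n_basis))
    },
    circspline = {
      v <- term$variables
      lo <- term$cycle_bounds[1]; hi <- term$cycle_bounds[2]
      B <- cyclic_spline_basis(ev[[v]], term$n_basis, lo, hi)
      knots <- attr(B, "knots")
      drop_idx <- NA_integer_; ref_x <- NA_real_
      if (has_intercept) {
        wrapped <- lo + (ev[[v]] - lo) %% (hi - lo)
        # cyclic basis j peaks at knot j (uniform knots)
        drop_idx <- which.min(abs(knots[seq_len(term$n_basis)] -
                                    median(wrapped)))
        ref_x <- knots[drop_idx]
        B <- B[, -drop_idx, drop = FALSE]
      }
      keep <- setdiff(seq_len(term$n_basis), drop_idx)
      list(values = B, labels = paste0(v, ".circ", keep), basis_index = keep,
           meta = list(knots = knots, dropped = drop_idx, ref_x = ref_x,
                       n_basis = term$n_basis, cycle_bounds = c(lo, hi)))
    },
    spline2d = {
      va <- term$variables[1]; vb <- term$variables[2]
      ka <- quantile_knots(ev[[va]], term$n_basis)
      kb <- quantile_knots(ev[[vb]], term$n_basis)
      B <- tensor_spline_basis(ev[[va]], ev[[vb]], term$n_basis, ka, kb)
      nb <- term$n_basis
      drop_idx <- NA_integer_; ref_x <- c(NA_real_, NA_real_)
      if (has_intercept) {
        pa <- bspline_peaks(ka); pb <- bspline_peaks(kb)
        ja <- which.min(abs(pa - median(ev[[va]])))
        jb <- which.min(abs(pb - median(ev[[vb]])))
        drop_idx <- (jb - 1L) * nb + ja
        ref_x <- c(pa[ja], pb[jb])
        B <- B[, -drop_idx, drop = FALSE]
      }
      keep <- setdiff(seq_len(nb * nb), drop_idx)
      list(values = B, labels = paste0(va, ".", vb, ".t", keep),
           basis_index = keep,
           meta = list(knots_a = ka, knots_b = kb, dropped = drop_idx,
                       ref_x = ref_x, n_basis = nb))
    },
    interaction = {
      parts <- lapply(term$parents, code_term, ev = ev,
                      ref_levels = ref_levels, has_intercept = has_intercept)
      a <- parts[[1]]; b <- parts[[2]]
      cols <- matrix(0, n, ncol(a$values) * ncol(b$values))
      labels <- character(ncol(cols))
      k <- 0L
      for (j in seq_len(ncol(b$values))) for (i in seq_len(ncol(a$values))) {
        k <- k + 1L
        cols[, k] <- a$values[, i] * b$values[, j]
        labels[k] <- paste0(a$labels[i], ":", b$labels[j])
      }
      list(values = cols, labels = labels, basis_index = seq_len(k),
           meta = NULL)
    },
    stop("cannot code term of kind '", term$kind, "'")
  )
}

#' Build the instance-level design matrix for one event type
#'
#' Expands the spec's parsed terms against the events of the spec's event
#' type: treatment coding yields one indicator column per non-reference
#' level (reference = alphabetically first, or as set in `ref_levels`);
#' effects coding yields sum-to-zero contrasts with the alphabetically last
#' level as the -1 row; continuous predictors are passed through uncentered;
#' spline terms are expanded through their basis with one basis column
#' removed for identifiability when an intercept is present (the column
#' whose peak lies closest to the predictor median); interaction columns are
#' elementwise products of the parents' coded columns.
#'
#' @param events event table (see [as_event_table()]); must contain no
#'   missing values in referenced predictors (see [impute_missing()]).
#' @param spec an `erp_model_spec`.
#' @return an object of class `erp_design` with elements `values` (dense
#'   matrix, one row per instance), `colmap` (data.frame with `term`,
#'   `kind`, `basis_index`, `label`), `term_meta` (per-term basis metadata),
#'   and `onsets` (instance onsets in seconds).
#' @export
build_design <- function(events, spec) {
  stopifnot(inherits(spec, "erp_model_spec"))
  events <- as_event_table(events)
  diag <- validate_spec(spec, events)
  if (length(diag)) stop("invalid model spec:\n  ", paste(diag, collapse = "\n  "))
  ev <- events[events$type == spec$event_type, , drop = FALSE]
  used <- unique(unlist(lapply(spec$terms, `[[`, "variables")))
  used <- intersect(used, names(ev))
  if (length(used) && any(is.na(ev[, used, drop = FALSE])))
    stop("missing predictor values: run impute_missing() first")
  has_intercept <- any(vapply(spec$terms, function(t)
    t$kind == "intercept", TRUE))
  blocks <- lapply(spec$terms, code_term, ev = ev,
                   ref_levels = spec$ref_levels,
                   has_intercept = has_intercept)
  values <- do.call(cbind, lapply(blocks, `[[`, "values"))
  colmap <- do.call(rbind, lapply(seq_along(blocks), function(i)
    data.frame(term = term_label(spec$terms[[i]]),
               kind = spec$terms[[i]]$kind,
               basis_index = blocks[[i]]$basis_index,
               label = blocks[[i]]$labels,
               stringsAsFactors = FALSE)))
  colmap$col <- seq_len(nrow(colmap))
  colnames(values) <- colmap$label
  term_meta <- stats::setNames(lapply(blocks, `[[`, "meta"),
                               vapply(spec$terms, term_label, ""))
  zero <- which(colSums(abs(values)) == 0)
  if (length(zero))
    warning("design column(s) identically zero: ",
            paste(colmap$label[zero], collapse = ", "))
  structure(list(values = values, colmap = colmap, term_meta = term_meta,
                 spec = spec, onsets = ev$onset, events = ev),
            class = "erp_design")
}

#' @export
print.erp_design <- function(x, ...) {
  cat(sprintf("<design> event type '%s': %d instances x %d columns\n",
              x$spec$event_type, nrow(x$values), ncol(x$values)))
  invisible(x)
}
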