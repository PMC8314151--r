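#' Score one case's predicted masks against ground truth
#'
#' Computes, organ by organ, the surface DSC at the organ's calibrated
#' tolerance and the volumetric DSC. Organs present in either the
#' prediction or the truth list are evaluated; an organ absent from one
#' side is treated as an empty mask on that side. A missing tolerance for
#' an evaluated organ is an error.
#'
#' @param pred named list of [binary_mask()] per organ (the prediction).
#' @param truth named list of [binary_mask()] per organ (the reference).
#' @param tolerances a [tolerance_set()] covering every evaluated organ.
#' @param case_id identifier recorded with every row.
#' @param role label of the comparison (e.g. `"model"` or
#'   `"radiographer"`).
#' @return a data.frame of comparison records, one row per organ, with
#'   columns `case_id`, `organ`, `role`, `tolerance_mm`, `surface_dsc`,
#'   `volumetric_dsc`, `surface_dsc_defined`, `volumetric_dsc_defined`.
#'   Undefined metric values (both masks empty) are `NA` with the flag set
#'   to `FALSE`.
#' @export
evaluate_case <- function(pred, truth, tolerances, case_id = "case",
                          role = "model") {
  stopifnot(inherits(tolerances, "tolerance_set"))
  organs <- union(names(pred), names(truth))
  if (length(organs) == 0L) stop("no organs to evaluate", call. = FALSE)
  missing_tol <- setdiff(organs, names(tolerances$tolerances))
  if (length(missing_tol) > 0L)
    stop("missing tolerance for organ(s): ",
         paste(missing_tol, collapse = ", "), call. = FALSE)

  template <- c(pred, truth)[[1]]
  empty <- binary_mask(array(FALSE, dim(template$grid)), template$spacing)
  table <- build_neighborhood_table(template$spacing)

  rows <- lapply(organs, function(organ) {
    p <- if (organ %in% names(pred)) pred[[organ]] else empty
    t <- if (organ %in% names(truth)) truth[[organ]] else empty
    tau <- tolerances$tolerances[[organ]]
    sd <- surface_dsc(p, t, tau, table)
    vd <- volumetric_dsc(p, t)
    data.frame(case_id = case_id, organ = organ, role = role,
               tolerance_mm = tau,
               surface_dsc = sd$value, volumetric_dsc = vd,
               surface_dsc_defined = !sd$undefined,
               volumetric_dsc_defined = !is.na(vd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# type-7 quartiles, 1.5 IQR whiskers, notch half-width 1.57 IQR / sqrt(n)
box_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  list(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(x[inside]), whisker_high = max(x[inside]),
       outliers = sort(x[!inside]),
       notch = 1.57 * iqr / sqrt(length(x)))
}

#' Per-organ cohort summary with paired comparator differences
#'
#' Produces for each organ the statistics of a notched box plot over the
#' primary role's surface DSC values: median, type-7 quartiles, whiskers
#' at the most extreme values within 1.5 IQR of the quartiles, outliers
#' beyond them, and a notch half-width of 1.57 IQR / sqrt(n)
#' (an approximate 95% CI around the median). When `pair_with` names a
#' comparator role, records are paired by (case_id, organ) and the mean
#' primary-minus-comparator difference is reported in percentage points
#' and classified against a +/-5 point band of non-substantial difference.
#'
#' Undefined metric values are excluded from all statistics and counted in
#' `n_undefined`; unpaired records are excluded from difference statistics
#' and counted in `n_unpaired`.
#'
#' @param records data.frame of comparison records from [evaluate_case()]
#'   (possibly row-bound over many cases and roles).
#' @param pair_with optional comparator role name present in `records`.
#' @param metric which metric column to summarize.
#' @return a data.frame with one row per organ: `organ`, `n`, `median`,
#'   `q1`, `q3`, `whisker_low`, `whisker_high`, `outliers`
#'   (semicolon-joined), `notch`, `n_undefined` and, when paired,
#'   `n_pairs`, `n_unpaired`, `mean_diff_pp`, `diff_class` (one of
#'   `"nonsubstantial"`, `"better"`, `"worse"`). Organs with no defined
#'   value have `n = 0` and `NA` statistics.
#' @export
summarize_cohort <- function(records, pair_with = NULL,
                             metric = c("surface_dsc", "volumetric_dsc")) {
  metric <- match.arg(metric)
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame", call. = FALSE)
  defined_col <- paste0(metric, "_defined")

  roles <- unique(records$role)
  if (!is.null(pair_with)) {
    if (!pair_with %in% roles)
      stop(sprintf("comparator role '%s' not present", pair_with),
           call. = FALSE)
    primary_roles <- setdiff(roles, pair_with)
    if (length(primary_roles) != 1L)
      stop("pairing needs exactly one primary role besides the comparator",
           call. = FALSE)
    primary <- records[records$role == primary_roles, , drop = FALSE]
    comp <- records[records$role == pair_with, , drop = FALSE]
  } else {
    primary <- records
    comp <- NULL
  }

  rows <- lapply(sort(unique(records$organ)), function(organ) {
    sub <- primary[primary$organ == organ, , drop = FALSE]
    vals <- sub[[metric]][sub[[defined_col]]]
    out <- data.frame(organ = organ, n = length(vals), median = NA_real_,
                      q1 = NA_real_, q3 = NA_real_,
                      whisker_low = NA_real_, whisker_high = NA_real_,
                      outliers = "", notch = NA_real_,
                      n_undefined = sum(!sub[[defined_col]]),
                      stringsAsFactors = FALSE)
    if (length(vals) >= 1L) {
      bs <- box_stats(vals)
      out$median <- bs$median; out$q1 <- bs$q1; out$q3 <- bs$q3
      out$whisker_low <- bs$whisker_low; out$whisker_high <- bs$whisker_high
      out$outliers <- paste(format(bs$outliers, digits = 6),
                            collapse = ";")
      out$notch <- bs$notch
    }
    if (!is.null(comp)) {
      co <- comp[comp$organ == organ, , drop = FALSE]
      merged <- merge(sub[, c("case_id", metric, defined_col)],
                      co[, c("case_id", metric, defined_col)],
                      by = "case_id", suffixes = c(".p", ".c"))
      ok <- merged[[paste0(defined_col, ".p")]] &
            merged[[paste0(defined_col, ".c")]]
      diffs <- 100 * (merged[[paste0(metric, ".p")]][ok] -
                      merged[[paste0(metric, ".c")]][ok])
      out$n_pairs <- sum(ok)
      out$n_unpaired <- nrow(sub) + nrow(co) - 2L * nrow(merged) +
        2L * sum(!ok)
      out$mean_diff_pp <- if (sum(ok) > 0L) mean(diffs) else NA_real_
      out$diff_class <- if (sum(ok) == 0L) NA_character_
        else if (abs(out$mean_diff_pp) <= 5) "nonsubstantial"
        else if (out$mean_diff_pp > 5) "better" else "worse"
    }
    out
  })
  do.call(rbind, rows)
}

#' Read a cohort manifest CSV
#'
#' The manifest lists the mask files of a cohort, one row per
#' (case, organ, role) with columns `case_id`, `organ`, `role`,
#' `mask_path`, `truth_path`. Relative paths are resolved against the
#' manifest's directory.
#'
#' @param path CSV file.
#' @return a data.frame with resolved paths.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "organ", "role", "mask_path", "truth_path")
  missing <- setdiff(need, names(m))
  if (length(missing) > 0L)
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  m$mask_path <- resolve(m$mask_path)
  m$truth_path <- resolve(m$truth_path)
  m
}

#' Evaluate a whole cohort from a manifest
#'
#' Reads every mask pair listed in the manifest, scores it with
#' [evaluate_case()] semantics, and returns the full record table. Cases
#' are grouped by (case_id, role); each group's organs are evaluated
#' together.
#'
#' @param manifest data.frame from [read_manifest()] (or of the same
#'   shape).
#' @param tolerances a [tolerance_set()].
#' @return a data.frame of comparison records.
#' @export
evaluate_cohort <- function(manifest, tolerances) {
  groups <- split(manifest,
                  interaction(manifest$case_id, manifest$role, drop = TRUE))
  rows <- lapply(groups, function(g) {
    pred <- truth <- list()
    for (i in seq_len(nrow(g))) {
      pred[[g$organ[i]]] <- read_mask(g$mask_path[i])
      truth[[g$organ[i]]] <- read_mask(g$truth_path[i])
    }
    evaluate_case(pred, truth, tolerances,
                  case_id = g$case_id[1], role = g$role[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write records or summaries as CSV
#'
#' Fixed column order, '.' decimal separator, floats at 6 significant
#' digits, so outputs are diffable across runs.
#'
#' @param x data.frame of records or summaries.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_report_csv <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], signif, digits = 6)
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
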