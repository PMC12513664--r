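# Stage stratification: map the five Hoehn & Yahr stages onto the
# three-stage (mild/moderate/advanced) model, compute population shares,
# the monitorable fraction, and split national totals into stage pools.

#' Hoehn & Yahr prevalence table
#'
#' @param region region identifier.
#' @param counts named numeric vector of non-negative counts for stages
#'   `I`..`V`.
#' @return an object of class `hy_table`.
#' @export
hy_table <- function(region, counts) {
  if (!is.character(region) || length(region) != 1L || !nzchar(region)) {
    pdbia_stop("region must be a non-empty string")
  }
  if (!is.numeric(counts) || !identical(sort(names(counts)), sort(HY_STAGES))) {
    pdbia_stop(sprintf("H&Y counts for %s must be named exactly I..V", region),
               "pdbia_schema_error")
  }
  counts <- counts[HY_STAGES]
  if (any(!vapply(counts, is_count, logical(1)))) {
    pdbia_stop(sprintf("H&Y counts for %s must be non-negative integers", region))
  }
  structure(list(region = region, counts = stats::setNames(as.numeric(counts), HY_STAGES)),
            class = "hy_table")
}

#' Read H&Y tables from a CSV file
#'
#' Expects columns `region, I, II, III, IV, V`, one row per region.
#'
#' @param path CSV file path.
#' @return a list of [hy_table()] objects.
#' @export
read_hy_tables <- function(path) {
  if (!file.exists(path)) pdbia_stop(sprintf("file not found: %s", path), "pdbia_io_error")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("region", HY_STAGES)
  if (!all(need %in% names(df))) {
    pdbia_stop(sprintf("H&Y CSV must have columns: %s", paste(need, collapse = ", ")),
               "pdbia_schema_error")
  }
  lapply(seq_len(nrow(df)), function(i) {
    hy_table(df$region[i], stats::setNames(as.numeric(df[i, HY_STAGES]), HY_STAGES))
  })
}

#' Three-stage shares from a H&Y table
#'
#' Mild patients are H&Y stages I-II, moderate is stage III, advanced is
#' stages IV-V; shares are computed over all diagnosed patients I-V.
#'
#' @param hy a [hy_table()].
#' @return a [stage_distribution()].
#' @export
stage_proportions_from_hy <- function(hy) {
  if (!inherits(hy, "hy_table")) pdbia_stop("expected an hy_table")
  total <- sum(hy$counts)
  if (total <= 0) {
    pdbia_stop(sprintf("H&Y table %s has zero total; stage distribution undefined",
                       hy$region), "pdbia_undefined_distribution_error")
  }
  k <- hy$counts
  stage_distribution(
    mild = (k[["I"]] + k[["II"]]) / total,
    moderate = k[["III"]] / total,
    advanced = (k[["IV"]] + k[["V"]]) / total
  )
}

#' Monitorable fraction of a patient population
#'
#' Stage-V patients are non-ambulatory and cannot be monitored by the
#' waist-worn inertial sensor; everyone in stages I-IV can.  Pooled over
#' the seven bundled regions this is 94.4%.
#'
#' @param tables list of [hy_table()] objects (pooled).
#' @return proportion in \[0,1\]: 1 - (pooled stage-V count)/(pooled total).
#' @examples
#' monitorable_fraction(bundled_hy_tables())  # 0.944...
#' @export
monitorable_fraction <- function(tables) {
  if (inherits(tables, "hy_table")) tables <- list(tables)
  if (!is.list(tables) || length(tables) < 1L) {
    pdbia_stop("need at least one H&Y table", "pdbia_precondition_error")
  }
  if (!all(vapply(tables, inherits, logical(1), "hy_table"))) {
    pdbia_stop("all elements must be hy_table objects")
  }
  counts <- Reduce(`+`, lapply(tables, `[[`, "counts"))
  total <- sum(counts)
  if (total <= 0) pdbia_stop("pooled total is zero", "pdbia_precondition_error")
  1 - counts[["V"]] / total
}

#' Split a national total into stage pools
#'
#' Unrounded pools are exact products `total * share` and always sum to the
#' total; display values are rounded half away from zero to integers.
#'
#' @param total national diagnosed total (>= 0).
#' @param dist a [stage_distribution()].
#' @return list with numeric vectors `unrounded` and `display`, both named
#'   by stage.
#' @examples
#' stratify_total(106475, stage_distribution())$display  # 47914 37266 21295
#' @export
stratify_total <- function(total, dist = stage_distribution()) {
  if (!is.numeric(total) || length(total) != 1L || !is.finite(total) || total < 0) {
    pdbia_stop("total must be a single non-negative number")
  }
  if (!inherits(dist, "stage_distribution")) {
    dist <- do.call(stage_distribution, as.list(dist))
  }
  unrounded <- as.numeric(dist) * total
  names(unrounded) <- STAGES
  list(unrounded = unrounded, display = round_half_away(unrounded))
}
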