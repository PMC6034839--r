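#' The size-based T-stage parameter table
#'
#' One row per TNM T category: the half-open diameter interval `(lo, hi]`
#' in mm that defines it, the mean primary-tumor volume doubling time
#' (TVDT, days) the model assigns to it, and the metastasis growth-rate
#' coefficient `k_smts` (the MTS clock runs at `tvdt / k_smts`; 1.00 for
#' node-negative disease, so PT and MTS grow at the same rate). T4 is not
#' size-determined (skin/chest-wall invasion), so its interval is `NA`; its
#' TVDT of 47 days is the midpoint of the model's 46-48 day range.
#'
#' Alternate tables with the same columns can be passed to
#' [classify_t_stage()] and [stage_parameters()], or loaded from a key-value
#' config file via [read_stage_table()].
#'
#' @return A `data.frame` with columns `label`, `lo`, `hi`, `tvdt_days`,
#'   `k_smts` and an attribute `version`.
#' @export
stage_table <- function() {
  tab <- data.frame(
    label     = c("T1a", "T1b", "T1c", "T2", "T3", "T4"),
    lo        = c(1, 5, 10, 20, 50, NA),
    hi        = c(5, 10, 20, 50, Inf, NA),
    tvdt_days = c(70, 70, 70, 65, 60, 47),
    k_smts    = c(1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  attr(tab, "version") <- "N0-v1"
  tab
}

validate_stage_table <- function(table) {
  need <- c("label", "lo", "hi", "tvdt_days", "k_smts")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("stage table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(table$tvdt_days <= 0) || any(table$k_smts <= 0))
    stop("stage table: tvdt_days and k_smts must be positive", call. = FALSE)
  sized <- table[!is.na(table$lo), , drop = FALSE]
  sized <- sized[order(sized$lo), , drop = FALSE]
  if (nrow(sized) && (any(diff(c(sized$lo, Inf)) < 0) ||
                      any(sized$hi[-nrow(sized)] != sized$lo[-1])))
    stop("stage table: diameter intervals must partition (lo1, Inf) without ",
         "gaps or overlap", call. = FALSE)
  invisible(table)
}

#' Classify the TNM T parameter from tumor diameter
#'
#' Assigns the unique size category whose half-open interval `(lo, hi]`
#' contains the diameter: T1a (1,5], T1b (5,10], T1c (10,20], T2 (20,50],
#' T3 (50, Inf). Right-closed exactly as the clinical definitions read
#' ("1 < d <= 5"), so a 5.0 mm tumor is T1a. T4 is never returned: it
#' requires non-size clinical findings.
#'
#' @param d Diameter at surgery, mm; must exceed 1 mm (smaller tumors are
#'   sub-visible and unstageable by size).
#' @param table Stage table, see [stage_table()].
#' @return Stage label, character scalar.
#' @examples
#' classify_t_stage(15.1)  # "T1c"
#' @export
classify_t_stage <- function(d, table = stage_table()) {
  validate_stage_table(table)
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d))
    stop("`d` must be a single finite number", call. = FALSE)
  sized <- table[!is.na(table$lo), , drop = FALSE]
  if (d <= min(sized$lo))
    stop("tumor of ", d, " mm is below the ", min(sized$lo),
         " mm staging threshold: unstageable by size", call. = FALSE)
  hit <- which(d > sized$lo & d <= sized$hi)
  if (length(hit) != 1L)   # unreachable with a validated table
    stop("stage intervals do not uniquely cover d = ", d, call. = FALSE)
  sized$label[hit]
}

#' Growth parameters for a stage and nodal status
#'
#' Looks up the per-stage TVDT and MTS-rate coefficient. Only node-negative
#' (N0) disease is supported: the model does not describe growth with
#' regional lymph-node metastases (T1-4 N1-3), and asking for `N+` is an
#' explicit error rather than a silent extrapolation.
#'
#' @param stage Stage label (e.g. `"T2"`), or the result of
#'   [classify_t_stage()].
#' @param nodal_status `"N0"` (supported) or `"N+"` (errors).
#' @param table Stage table, see [stage_table()].
#' @return An object of class `compas_stage_params`: list with `stage`,
#'   `tvdt_days`, `k_smts`.
#' @examples
#' stage_parameters("T2")  # TVDT 65 d, k 1.00
#' @export
stage_parameters <- function(stage, nodal_status = c("N0", "N+"),
                             table = stage_table()) {
  validate_stage_table(table)
  nodal_status <- match.arg(nodal_status)
  if (nodal_status == "N+")
    stop("node-positive disease (N+) is outside the model's validity: ",
         "growth with regional lymph-node metastases is not described",
         call. = FALSE)
  row <- which(table$label == stage)
  if (length(row) != 1L)
    stop("unknown stage label: ", stage, call. = FALSE)
  structure(list(stage = table$label[row],
                 tvdt_days = table$tvdt_days[row],
                 k_smts = table$k_smts[row]),
            class = "compas_stage_params")
}

#' @export
print.compas_stage_params <- function(x, ...) {
  cat(sprintf("Stage %s (N0): TVDT %.1f days, k_sMTS %.2f\n",
              x$stage, x$tvdt_days, x$k_smts))
  invisible(x)
}

#' Read a stage table from a flat key-value config file
#'
#' Each non-comment line reads `label lo hi tvdt_days k_smts`, whitespace
#' separated; `Inf` and `NA` are accepted for the bounds. Lines starting
#' with `#` are ignored.
#'
#' @param path Path to the config file.
#' @return A validated stage table `data.frame`.
#' @export
read_stage_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    stop("empty stage-table config: ", path, call. = FALSE)
  parts <- strsplit(lines, "[[:space:],]+")
  bad <- which(lengths(parts) != 5L)
  if (length(bad))
    stop("stage-table config line ", bad[1], " needs 5 fields: '",
         lines[bad[1]], "'", call. = FALSE)
  tab <- data.frame(
    label     = vapply(parts, `[`, "", 1L),
    lo        = as.numeric(vapply(parts, `[`, "", 2L)),
    hi        = as.numeric(vapply(parts, `[`, "", 3L)),
    tvdt_days = as.numeric(vapply(parts, `[`, "", 4L)),
    k_smts    = as.numeric(vapply(parts, `[`, "", 5L)),
    stringsAsFactors = FALSE
  )
  validate_stage_table(tab)
  tab
}
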