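# Readers/writers for gas-exchange tables and summary reports.
#
# The native on-disk format is plain CSV preceded by a '#'-prefixed
# key: value metadata header block -- diff-able and instrument-agnostic.

.GASEX_COLS <- c("time_s", "ppfd", "ca_umol_mol", "a_umol_m2_s",
                 "gsw_mol_m2_s", "ci_umol_mol", "tleaf_c", "vpd_kpa")

# LI-6400 vendor column names -> native schema
.LI6400_MAP <- c(Photo = "a_umol_m2_s", Cond = "gsw_mol_m2_s",
                 Ci = "ci_umol_mol", PARi = "ppfd", Tleaf = "tleaf_c",
                 VpdL = "vpd_kpa", PhiPS2 = "phipsii", CO2R = "ca_umol_mol",
                 FTime = "time_s")

#' Construct a gas-exchange trace
#'
#' A `gasex_trace` is a data frame of time-stamped drivers and fluxes from
#' one leaf with fixed column names and units: `time_s`, `ppfd`
#' (umol m-2 s-1), `ca_umol_mol`, `a_umol_m2_s`, `gsw_mol_m2_s`,
#' `ci_umol_mol`, `tleaf_c`, `vpd_kpa` and optionally `phipsii`.
#'
#' @param df data frame holding the required columns.
#' @param cultivar,replicate,protocol optional metadata strings.
#' @return the validated trace, classed `gasex_trace`.
#' @export
gasex_trace <- function(df, cultivar = NA_character_,
                        replicate = NA_character_,
                        protocol = NA_character_) {
  missing <- setdiff(.GASEX_COLS, names(df))
  if (length(missing) > 0) {
    stop("gas-exchange trace is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop("'time_s' must be strictly increasing")
  }
  structure(as.data.frame(df),
            cultivar = cultivar, replicate = replicate, protocol = protocol,
            class = c("gasex_trace", "data.frame"))
}

#' Read a gas-exchange trace from disk
#'
#' @param path file path.
#' @param dialect `"native"` (CSV with a `#` metadata header) or `"li6400"`
#'   (tabular export with vendor column names Photo, Cond, Ci, PARi, Tleaf,
#'   VpdL, PhiPS2, CO2R, FTime).
#' @return a [gasex_trace()].
#' @export
read_gasex <- function(path, dialect = c("native", "li6400")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    if (nzchar(key)) meta[[key]] <- val
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        check.names = FALSE)
  if (dialect == "li6400") {
    hit <- names(df) %in% names(.LI6400_MAP)
    names(df)[hit] <- .LI6400_MAP[names(df)[hit]]
  }
  gasex_trace(df,
              cultivar = if (is.null(meta$cultivar)) NA_character_ else meta$cultivar,
              replicate = if (is.null(meta$replicate)) NA_character_ else meta$replicate,
              protocol = if (is.null(meta$protocol)) NA_character_ else meta$protocol)
}

#' Write a gas-exchange trace in the native CSV format
#'
#' Numeric columns are written with 6 significant digits, which round-trips
#' stably through [read_gasex()].
#'
#' @param trace a [gasex_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gasex <- function(trace, path) {
  stopifnot(inherits(trace, "gasex_trace"))
  meta <- c(cultivar = attr(trace, "cultivar"),
            replicate = attr(trace, "replicate"),
            protocol = attr(trace, "protocol"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    if (!is.na(meta[[k]])) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  }
  out <- as.data.frame(trace)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Summarize per-replicate results per cultivar (mean +/- SE)
#'
#' @param df data frame of per-replicate metrics; one row per replicate.
#' @param group name of the grouping column (default `"cultivar"`).
#' @return data frame with one row per group and, for every numeric metric,
#'   `<metric>_mean` and `<metric>_se` columns. The SE is `NA` (blank on
#'   output), not zero, for single-replicate groups.
#' @export
summarize_replicates <- function(df, group = "cultivar") {
  if (nrow(df) == 0) {
    return(data.frame())
  }
  stopifnot(group %in% names(df))
  metrics <- names(df)[vapply(df, is.numeric, logical(1))]
  metrics <- setdiff(metrics, group)
  groups <- unique(df[[group]])
  out <- data.frame(stats::setNames(list(groups), group))
  for (m in metrics) {
    means <- ses <- numeric(length(groups))
    for (i in seq_along(groups)) {
      x <- df[df[[group]] == groups[i], m]
      x <- x[is.finite(x)]
      means[i] <- mean(x)
      ses[i] <- if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_
    }
    out[[paste0(m, "_mean")]] <- means
    out[[paste0(m, "_se")]] <- ses
  }
  out
}

#' Published cassava summary tables shipped as fixtures
#'
#' Per-cultivar mean +/- SE summary tables for 13 African cassava cultivars:
#' steady-state gas exchange (`"steady_state"`: Asat, Vcmax, Vcmax_Cc, Jmax,
#' V_TPU, gs, iWUE, operating ci), leaf biochemistry (`"biochem"`: Rubisco
#' content and activities), and induction metrics (`"induction"`: T50A,
#' T90A, CCF, gsT0, T50gs). These are transcriptions of printed
#' literature tables, shipped as plain CSV under `extdata/` and used as
#' reference inputs for summary arithmetic; they are not instrument data.
#'
#' @param which one of `"steady_state"`, `"biochem"`, `"induction"`.
#' @return data frame with a `cultivar` column plus `<metric>_mean` /
#'   `<metric>_se` columns.
#' @export
cassava_reference_table <- function(which = c("steady_state", "biochem",
                                              "induction")) {
  which <- match.arg(which)
  fn <- c(steady_state = "cassava_steady_state_summary.csv",
          biochem = "cassava_biochem_summary.csv",
          induction = "cassava_induction_summary.csv")[[which]]
  path <- system.file("extdata", fn, package = "cassleaf")
  if (!nzchar(path)) stop("fixture table not found: ", fn)
  utils::read.csv(path, check.names = FALSE)
}

#' Optional diffusive-leak correction for cuvette gas exchange
#'
#' Linear correction `A + k_leak * (Ca - chamber_ambient)` for diffusion
#' between the cuvette and the surrounding air, relevant at the extremes
#' of a CO2 staircase. Off by default (`k_leak = 0`) because the constant
#' is instrument- and gasket-specific and must be calibrated with an
#' empty chamber.
#'
#' @param A measured net assimilation (umol m-2 s-1), vectorized.
#' @param Ca cuvette CO2 (umol mol-1), same length.
#' @param k_leak leak conductance (mol m-2 s-1); 0 disables.
#' @param chamber_ambient CO2 of the air surrounding the chamber
#'   (umol mol-1).
#' @return corrected assimilation.
#' @export
leak_correct <- function(A, Ca, k_leak = 0, chamber_ambient = 400) {
  stopifnot(k_leak >= 0)
  A + k_leak * (Ca - chamber_ambient)
}
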