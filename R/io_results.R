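#' Write a results bundle to disk
#'
#' Writes laterality results as CSV (one row per brain and region, whole
#' hemispheres reported under region `"all"`), mediolateral profiles as CSV
#' (one row per bin), and group statistics as JSON. Numbers are written with
#' 15 significant digits so re-reading reproduces values to full precision.
#'
#' @param results list with any of the components `laterality` (data.frame
#'   with columns `brain`, `region`, `n_ipsi`, `n_contra`, `n_on_plane`,
#'   `n_excluded`, `LI`, `contralateral_fraction`), `profiles` (data.frame
#'   with `brain`, `bin`, `bin_mid`, `density`), `group_stats` (list, e.g. a
#'   [mann_whitney_two_sided()] result plus group summaries).
#' @param out_dir output directory, created if missing.
#' @return named character vector of files written, invisibly.
#' @export
write_results <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop(sprintf("cannot create output directory %s", out_dir), call. = FALSE)
    }
  }
  written <- character(0)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
    df[num] <- lapply(df[num], function(x) signif(x, 15))
    df
  }
  if (!is.null(results$laterality)) {
    f <- file.path(out_dir, "laterality.csv")
    utils::write.csv(fmt(as.data.frame(results$laterality)), f, row.names = FALSE)
    written["laterality"] <- f
  }
  if (!is.null(results$profiles)) {
    f <- file.path(out_dir, "profiles.csv")
    utils::write.csv(fmt(as.data.frame(results$profiles)), f, row.names = FALSE)
    written["profiles"] <- f
  }
  if (!is.null(results$group_stats)) {
    f <- file.path(out_dir, "group_stats.json")
    jsonlite::write_json(results$group_stats, f, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    written["group_stats"] <- f
  }
  invisible(written)
}

# Flatten a whole-cloud laterality result and a per-region table into the
# one-row-per-brain-and-region layout of laterality.csv.
laterality_rows <- function(brain, lat, regional = NULL) {
  rows <- data.frame(brain = brain, region = "all",
                     n_ipsi = lat$n_ipsi, n_contra = lat$n_contra,
                     n_on_plane = lat$n_on_plane, n_excluded = lat$n_excluded,
                     LI = lat$LI, contralateral_fraction = NA_real_,
                     stringsAsFactors = FALSE)
  if (!is.null(regional)) {
    rr <- as.data.frame(regional)
    rows <- rbind(rows, data.frame(
      brain = brain, region = rr$region,
      n_ipsi = rr$n_ipsi, n_contra = rr$n_contra,
      n_on_plane = NA_integer_, n_excluded = NA_integer_,
      LI = NA_real_, contralateral_fraction = rr$contralateral_fraction,
      stringsAsFactors = FALSE))
  }
  rows
}

profile_rows <- function(brain, profile) {
  n <- length(profile$density)
  data.frame(brain = brain, bin = seq_len(n),
             bin_mid = (profile$bin_edges[-1] + profile$bin_edges[-(n + 1)]) / 2,
             density = profile$density,
             stringsAsFactors = FALSE)
}
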