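#' Select a core marker panel by discriminating power
#'
#' Filters a marker-statistics table with the four panel-design criteria
#' used for fingerprinting work: strong discriminating power
#' (`pid < pid_max`), high polymorphism (`pic > pic_min`), and manageable
#' allele/genotype counts (`na <= na_max`, `ng <= ng_max`). The PID and PIC
#' bounds are strict, the count bounds inclusive, so a marker sitting
#' exactly on the PID threshold is rejected. The surviving markers are
#' returned in descending PID order (ties broken by name), which is the
#' order in which an identification diagram consumes them.
#'
#' @param stats a `marker_stats` data frame (columns `marker`, `pid`,
#'   `pic`, `na`, `ng`), e.g. [tea_marker_stats()] or
#'   [summarize_markers()] output.
#' @param pid_max strict upper bound on the probability of identity.
#'   The default 0.198 is the panel-average PID reported for the packaged
#'   33-marker tea panel; pass [panel_mean_pid()] of your own table to use
#'   a recomputed mean instead.
#' @param pic_min strict lower bound on polymorphism information content.
#' @param na_max,ng_max inclusive upper bounds on the number of alleles and
#'   of genotypes.
#' @return character vector of selected marker names, descending PID. An
#'   empty selection is legal and returned with a warning.
#' @examples
#' select_core_markers(tea_marker_stats())
#' @export
select_core_markers <- function(stats, pid_max = 0.198, pic_min = 0.5,
                                na_max = 5, ng_max = 10) {
  df <- as.data.frame(stats)
  needed <- c("marker", "pid", "pic", "na", "ng")
  if (nrow(df) == 0L || !all(needed %in% names(df)))
    stop("'stats' must be a non-empty marker statistics table", call. = FALSE)
  stopifnot(pid_max > 0, pic_min >= 0, na_max >= 2, ng_max >= 1)
  keep <- df$pid < pid_max & df$pic > pic_min & df$na <= na_max &
    df$ng <= ng_max
  sel <- df[keep, ]
  sel <- sel[order(-sel$pid, sel$marker), ]
  if (nrow(sel) == 0L)
    warning("no marker satisfies the selection criteria", call. = FALSE)
  sel$marker
}

#' Mean probability of identity of a marker panel
#'
#' @param stats a `marker_stats` data frame with a `pid` column.
#' @return arithmetic mean of the per-locus PID values.
#' @export
panel_mean_pid <- function(stats) {
  df <- as.data.frame(stats)
  if (nrow(df) == 0L || !"pid" %in% names(df))
    stop("'stats' must be a non-empty marker statistics table", call. = FALSE)
  mean(df$pid)
}
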