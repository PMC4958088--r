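#' Run the full fingerprinting pipeline
#'
#' Replays the complete analysis on a genotype table: per-marker
#' statistics, core-panel selection from a marker-statistics table,
#' Nei-distance UPGMA dendrogram, and the cultivar identification diagram
#' over the selected panel — writing a deterministic artifact bundle to
#' `dir`:
#'
#' * `marker_stats.csv` — statistics recomputed from the genotype table
#'   (with a mean row),
#' * `core_markers.csv` — the selected panel, descending PID,
#' * `tree.nwk` — the UPGMA dendrogram in Newick form,
#' * `cid.json`, `cid.dot` — the identification diagram,
#' * `report.txt` — a plain-text run summary.
#'
#' With the defaults the pipeline reproduces the packaged tea study: core
#' selection runs on the published 33-marker statistics table, and the
#' diagram is built over the six selected markers present in the 66 x 6
#' genotype table. Any stage failure aborts the run with the stage name
#' and removes partial outputs.
#'
#' @param genotypes a [genotype_table()]; default [tea_genotypes()].
#' @param stats `marker_stats` table used for core selection and marker
#'   ordering; default [tea_marker_stats()]. Markers selected but absent
#'   from `genotypes` are dropped with a message.
#' @param dir output directory, created if needed.
#' @param pid_max,pic_min,na_max,ng_max selection thresholds, see
#'   [select_core_markers()].
#' @param metric distance metric for the dendrogram, see [nei_dist()].
#' @param cut_height height at which the dendrogram cut reported in
#'   `report.txt` is taken.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `stats`, `core`, `tree`, `cid`,
#'   `clusters` and the output `files`.
#' @examples
#' \donttest{
#' out <- run_pipeline(dir = tempfile("run"))
#' out$core
#' }
#' @export
run_pipeline <- function(genotypes = tea_genotypes(),
                         stats = tea_marker_stats(),
                         dir,
                         pid_max = 0.198, pic_min = 0.5,
                         na_max = 5, ng_max = 10,
                         metric = c("nei", "share"),
                         cut_height = 0.25,
                         quiet = FALSE) {
  metric <- match.arg(metric)
  stopifnot(inherits(genotypes, "genotype_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  out_file <- function(name) {
    p <- file.path(dir, name)
    written <<- c(written, p)
    p
  }

  say("computing marker statistics ...")
  computed <- stage("marker statistics", {
    s <- summarize_markers(genotypes)
    write_marker_stats(s, out_file("marker_stats.csv"))
    s
  })

  say("selecting core markers ...")
  core <- stage("core selection", {
    sel <- select_core_markers(stats, pid_max = pid_max, pic_min = pic_min,
                               na_max = na_max, ng_max = ng_max)
    absent <- setdiff(sel, marker_names(genotypes))
    if (length(absent) > 0L) {
      say("selected markers without genotype data dropped: ",
          paste(absent, collapse = ", "))
      sel <- setdiff(sel, absent)
    }
    if (length(sel) == 0L) stop("no selected marker has genotype data")
    utils::write.csv(data.frame(rank = seq_along(sel), marker = sel),
                     out_file("core_markers.csv"), row.names = FALSE,
                     quote = FALSE)
    sel
  })

  say("building UPGMA dendrogram (", metric, " distance) ...")
  tree_out <- stage("distance tree", {
    tree <- upgma(nei_dist(genotypes, method = metric))
    write_newick(tree, out_file("tree.nwk"))
    list(tree = tree, clusters = cut_tree(tree, cut_height))
  })

  say("building identification diagram ...")
  fit <- stage("cid", {
    f <- cid(genotypes, markers = core)
    cid_to_json(f, out_file("cid.json"))
    cid_to_dot(f, out_file("cid.dot"))
    f
  })

  stage("report", {
    s <- summary(fit)
    rep <- c(
      sprintf("Cultivars: %d  Markers genotyped: %d", n_cultivars(genotypes),
              length(marker_names(genotypes))),
      sprintf("Core panel (descending PID): %s", paste(core, collapse = ", ")),
      sprintf("Combined PID of the core panel: %.3g",
              combined_pid(as.data.frame(stats)$pid[
                match(core, as.data.frame(stats)$marker)])),
      sprintf("Dendrogram clusters at height %.3g: %d", cut_height,
              length(tree_out$clusters)),
      sprintf("CID root genotype groups: %d", s$n_root_groups),
      sprintf("Cultivars uniquely resolved: %d of %d",
              sum(s$paths$resolved), nrow(s$paths)),
      sprintf("Unresolved groups: %d", length(s$unresolved)))
    writeLines(rep, out_file("report.txt"))
  })

  say("done: ", dir)
  invisible(list(stats = computed, core = core, tree = tree_out$tree,
                 clusters = tree_out$clusters, cid = fit, files = written))
}
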