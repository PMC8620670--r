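# End-to-end orchestration: checklist + tree -> tabulations, NTI per
# assemblage, between-assemblage MNTD and PCoA, with a structured log.

#' Pipeline run configuration
#'
#' @param checklist_path path to a checklist CSV (see [read_checklist()]).
#' @param tree_path path to a Newick tree covering the checklist species.
#' @param output_dir directory for result files (created if absent).
#' @param n_draws null-model draws per assemblage (default 1000).
#' @param seed master seed; all stage seeds derive from it and are logged.
#' @param exclude_conspecifics passed to [comdistnt()]; the default keeps
#'   shared species at distance 0, the convention of the reference
#'   implementation, which matters for nested assemblages.
#' @param degenerate_null how [nti()] resolves a constant null (alien
#'   assemblage = pool): `"flag"` or `"bootstrap"`.
#' @param drop_threshold abort if more than this fraction of any assemblage
#'   is missing from the tree (default 0.2).
#' @param report_precision decimal places for percentages in the run
#'   summary (raw CSVs keep full precision).
#' @return A `run_config` list.
#' @export
run_config <- function(checklist_path, tree_path, output_dir,
                       n_draws = 1000L, seed = NULL,
                       exclude_conspecifics = FALSE,
                       degenerate_null = c("flag", "bootstrap"),
                       drop_threshold = 0.2, report_precision = 1L) {
  degenerate_null <- match.arg(degenerate_null)
  stopifnot(n_draws >= 1L, drop_threshold >= 0, drop_threshold <= 1)
  structure(list(checklist_path = checklist_path, tree_path = tree_path,
                 output_dir = output_dir, n_draws = as.integer(n_draws),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 exclude_conspecifics = isTRUE(exclude_conspecifics),
                 degenerate_null = degenerate_null,
                 drop_threshold = drop_threshold,
                 report_precision = as.integer(report_precision)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @param ... overrides applied on top of the file values.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' Run the full checklist-phylogeny analysis
#'
#' Stages: load and validate inputs; normalize lifeforms; derive the five
#' nested assemblages; match species to tree tips (spaces to underscores),
#' dropping and logging unmatched names, aborting if more than
#' `drop_threshold` of any assemblage is lost; tabulate family / lifeform /
#' origin / pathway composition per assemblage; per-family transition rates;
#' NTI of each assemblage against the alien reference pool; the 5x5
#' between-assemblage nearest-taxon distance matrix and its PCoA.
#'
#' Outputs written to `config$output_dir`: `tabulations.csv`,
#' `transition_rates.csv`, `nti.csv`, `nti.json`,
#' `assemblage_distances.csv`, `pcoa_coordinates.csv`, `pcoa_eigen.json`
#' and a JSON-lines `log.jsonl` (stage, counts, seeds, warnings; no
#' wall-clock fields, so identical inputs give byte-identical outputs).
#' On any stage error, files written by this run are removed.
#'
#' @param config a [run_config()].
#' @return Invisibly, a `run_summary` list: `assemblages` (counts),
#'   `dropped`, `nti` (data frame), `distances`, `pcoa`, `seeds`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  log_entries <- list()
  log_stage <- function(stage, ...) {
    log_entries[[length(log_entries) + 1L]] <<- c(list(stage = stage), list(...))
  }
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  fail <- function(stage, msg) {
    unlink(written)
    stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) fail(stage, conditionMessage(e)))
  }

  seeds <- list(master = config$seed,
                nti = if (is.null(config$seed)) NULL else config$seed)

  # --- load ---------------------------------------------------------------
  checklist <- run_stage("load_checklist", {
    normalize_lifeform(read_checklist(config$checklist_path))
  })
  tree <- run_stage("load_tree", read_newick(config$tree_path))
  log_stage("load", n_species = nrow(checklist), n_tips = length(tree$tip.label))

  # --- assemblages and tip matching ---------------------------------------
  assemblages <- run_stage("assemblages", derive_assemblages(checklist))
  dm <- run_stage("patristic", patristic_matrix(tree))
  matched <- list()
  dropped <- list()
  run_stage("tip_match", {
    for (nm in assemblage_names) {
      m <- match_tree_tips(assemblages[[nm]], tree)
      matched[[nm]] <- m$matched
      dropped[[nm]] <- m$dropped
      frac <- length(m$dropped) / max(1L, length(assemblages[[nm]]))
      if (frac > config$drop_threshold)
        stop(sprintf("%.1f%% of the %s assemblage is missing from the tree (threshold %.1f%%)",
                     100 * frac, nm, 100 * config$drop_threshold))
      if (length(m$matched) < 2L)
        stop(sprintf("fewer than 2 %s species matched to the tree", nm))
    }
  })
  log_stage("tip_match",
            matched = lapply(matched, length),
            dropped = lapply(dropped, length),
            dropped_names = unname(unique(unlist(dropped))))

  # --- tabulations ---------------------------------------------------------
  tab <- run_stage("tabulate", {
    do.call(rbind, lapply(assemblage_names, function(nm) {
      do.call(rbind, lapply(c("family", "lifeform", "origin", "pathway"),
        function(f) cbind(assemblage = nm,
                          tabulate_by(checklist, f, assemblages[[nm]]))))
    }))
  })
  emit("tabulations.csv", function(p)
    utils::write.csv(tab, p, row.names = FALSE))
  rates <- run_stage("transition_rates", transition_rates(checklist))
  emit("transition_rates.csv", function(p)
    utils::write.csv(rates, p, row.names = FALSE))
  log_stage("tabulate", n_rows = nrow(tab), n_families = nrow(rates))

  # --- NTI -----------------------------------------------------------------
  nti_res <- run_stage("nti", suppressMessages(
    nti_all(dm, matched, n_draws = config$n_draws, seed = seeds$nti,
            degenerate = config$degenerate_null)))
  nti_df <- as.data.frame(nti_res)
  emit("nti.csv", function(p) utils::write.csv(nti_df, p, row.names = FALSE))
  emit("nti.json", function(p)
    jsonlite::write_json(nti_df, p, auto_unbox = FALSE, digits = NA,
                         na = "null"))
  log_stage("nti", n_draws = config$n_draws,
            seeds = stats::setNames(as.list(nti_df$seed), nti_df$assemblage),
            degenerate = nti_df$assemblage[nti_df$degenerate])

  # --- between-assemblage distances and PCoA -------------------------------
  adm <- run_stage("comdistnt",
    assemblage_distance_matrix(dm, matched,
      exclude_conspecifics = config$exclude_conspecifics))
  emit("assemblage_distances.csv", function(p)
    utils::write.csv(adm, p, row.names = TRUE))
  ord <- run_stage("pcoa", pcoa(adm))
  emit("pcoa_coordinates.csv", function(p) {
    df <- data.frame(assemblage = rownames(ord$coordinates),
                     ord$coordinates, check.names = FALSE)
    utils::write.csv(df, p, row.names = FALSE)
  })
  emit("pcoa_eigen.json", function(p)
    jsonlite::write_json(list(eigenvalues = ord$eigenvalues,
                              variance_explained = ord$variance_explained,
                              negative_eigenvalue_mass = ord$negative_eigenvalue_mass),
                         p, digits = NA))
  log_stage("comdistnt", exclude_conspecifics = config$exclude_conspecifics)
  log_stage("pcoa", retained_axes = ncol(ord$coordinates),
            variance_explained = as.numeric(ord$variance_explained))

  emit("log.jsonl", function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    for (entry in log_entries)
      writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA,
                                  null = "null"), con)
  })

  invisible(structure(list(
    assemblages = vapply(assemblages[assemblage_names], length, integer(1)),
    matched = vapply(matched, length, integer(1)),
    dropped = dropped,
    nti = nti_df,
    distances = adm,
    pcoa = ord,
    seeds = seeds,
    files = written,
    report_precision = config$report_precision
  ), class = "run_summary"))
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Alien-flora phylogenetic analysis\n")
  cat("  assemblage sizes:",
      paste(sprintf("%s %d", names(x$assemblages), x$assemblages),
            collapse = ", "), "\n")
  n_drop <- length(x$dropped[["alien"]])
  if (n_drop) cat(sprintf("  species dropped (not on tree): %d\n", n_drop))
  cat("  NTI by assemblage:\n")
  df <- x$nti
  for (i in seq_len(nrow(df)))
    cat(sprintf("    %-12s %s\n", df$assemblage[i],
                if (is.na(df$nti[i])) "undefined (degenerate null)"
                else sprintf("%.3f", df$nti[i])))
  ve <- x$pcoa$variance_explained
  if (length(ve) >= 2L)
    cat(sprintf("  PCoA axes 1-2 variance explained: %s%%\n",
                format(round(100 * sum(ve[1:2]), x$report_precision))))
  invisible(x)
}
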