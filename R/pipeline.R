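#' Full-pipeline run configuration
#'
#' Defaults follow the method's stated conventions: upstream discovery region
#' (-500, 0), near-TSS region (-50, +150), pair region (-500, +150), top 50
#' genes for candidate enumeration, 8-bp words, top 5% seeds, two mismatches
#' for grouping, ratio cap 10, up-regulation threshold 2, negative
#' undersampling 1/16.
#'
#' @param scoring a [scoring_params()]
#' @param sim a [sim_config()]
#' @param upstream_region,neartss_region,pair_region TSS-relative windows
#' @param top_k,word,top_fraction,max_mismatch discovery parameters
#' @param n_mp number of motif pairs used as features
#' @param max_motifs cap on the number of motif groups per discovery pass
#'   carried into co-localization and simulation (NULL = all groups); dense
#'   low-rank noise groups dilute the classifier, so the default keeps the 30
#'   strongest, matching the depth at which motif tables are reported
#' @param seed master seed
#' @return object of class `run_config`
#' @export
run_config <- function(scoring = scoring_params(), sim = sim_config(),
                       upstream_region = c(-500L, 0L),
                       neartss_region = c(-50L, 150L),
                       pair_region = c(-500L, 150L),
                       top_k = 50L, word = 8L, top_fraction = 0.05,
                       max_mismatch = 2L, n_mp = 0L, max_motifs = 30L,
                       seed = 1L) {
  stopifnot(inherits(scoring, "mama_params"), inherits(sim, "sim_config"))
  if (top_fraction < 0 || top_fraction > 1) stop("top_fraction must be in [0,1]")
  if (word < 1L || word > 16L) stop("word must be in 1..16")
  structure(list(scoring = scoring, sim = sim,
                 upstream_region = as.integer(upstream_region),
                 neartss_region = as.integer(neartss_region),
                 pair_region = as.integer(pair_region),
                 top_k = as.integer(top_k), word = as.integer(word),
                 top_fraction = top_fraction,
                 max_mismatch = as.integer(max_mismatch),
                 n_mp = as.integer(n_mp), max_motifs = max_motifs,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_manifest <- function(outdir, config, extra = list()) {
  jsonlite::write_json(
    c(list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
           seed = config$seed,
           package_version = as.character(utils::packageVersion("mama")),
           config = unclass_deep(config)), extra),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, null = "null")
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

# discovery pass restricted to one region: enumerate from the top genes,
# score, rank, group
discover_region <- function(promoters, expr, region, config) {
  pr <- subset_region(promoters, region)
  cands <- enumerate_candidates(pr, expr, top_k = config$top_k,
                                word = config$word)
  scores <- mama_score(cands, pr, expr, config$scoring)
  ranked <- rank_candidates(scores)
  groups <- group_motifs(ranked, top_fraction = config$top_fraction,
                         max_mismatch = config$max_mismatch)
  if (!is.null(config$max_motifs) && length(groups) > config$max_motifs)
    groups <- groups[seq_len(config$max_motifs)]
  list(ranked = ranked, groups = groups)
}

#' Discover motifs (upstream and near-TSS passes)
#'
#' Runs candidate enumeration, scoring, ranking, and grouping twice: once on
#' the upstream window and once on the near-TSS window. Writes ranked score
#' tables, group tables, and MEME-format matrices when `outdir` is given.
#'
#' @param promoters a [promoter_set()] covering both regions
#' @param expr an [expression_table()]
#' @param config a [run_config()]
#' @param outdir optional output directory
#' @return list(upstream = list(ranked, groups), neartss = list(ranked, groups))
#' @export
cmd_discover <- function(promoters, expr, config = run_config(),
                         outdir = NULL) {
  upstream <- discover_region(promoters, expr, config$upstream_region, config)
  neartss <- discover_region(promoters, expr, config$neartss_region, config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(upstream$ranked, file.path(outdir, "scores_upstream.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(neartss$ranked, file.path(outdir, "scores_neartss.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    groups_table(upstream$groups, file.path(outdir, "groups_upstream.tsv"))
    groups_table(neartss$groups, file.path(outdir, "groups_neartss.tsv"))
    write_meme(upstream$groups, file.path(outdir, "motifs_upstream.meme"))
    write_meme(neartss$groups, file.path(outdir, "motifs_neartss.meme"))
    write_manifest(outdir, config, list(stage = "discover"))
  }
  list(upstream = upstream, neartss = neartss)
}

#' Evaluate co-localization of discovered motifs
#'
#' @param discovered result of [cmd_discover()]
#' @inheritParams cmd_discover
#' @return list(pair_table, selection)
#' @export
cmd_coloc <- function(discovered, promoters, expr, config = run_config(),
                      outdir = NULL) {
  groups <- c(discovered$upstream$groups, discovered$neartss$groups)
  # drop duplicate seeds across the two passes
  groups <- groups[!duplicated(vapply(groups, `[[`, character(1), "seed"))]
  labels <- make_labels(expr, config$sim$up_threshold)
  up <- setNames(labels > 0, names(labels))
  pair_table <- evaluate_pairs(groups, promoters, up,
                               region = config$pair_region)
  selection <- select_enriched_pairs(pair_table, config$n_mp)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(pair_table, file.path(outdir, "pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(selection, file.path(outdir, "pairs_selected.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(pair_table = pair_table, selection = selection, groups = groups)
}

#' Simulate gene expression from motif/pair features
#'
#' @param discovered result of [cmd_discover()]
#' @param coloc optional result of [cmd_coloc()] (supplies pair features)
#' @inheritParams cmd_discover
#' @return a `sim_result`
#' @export
cmd_simulate <- function(discovered, promoters, expr, config = run_config(),
                         coloc = NULL, outdir = NULL) {
  pair_groups <- NULL; pairs <- NULL
  if (!is.null(coloc) && nrow(coloc$selection) > 0L) {
    pairs <- coloc$selection
    pair_groups <- setNames(coloc$groups,
                            vapply(coloc$groups, `[[`, character(1), "name"))
  }
  X <- build_features(promoters,
                      upstream_motifs = discovered$upstream$groups,
                      neartss_motifs = discovered$neartss$groups,
                      pairs = pairs, pair_groups = pair_groups,
                      upstream_region = config$upstream_region,
                      neartss_region = config$neartss_region,
                      pair_region = config$pair_region)
  labels <- make_labels(expr, config$sim$up_threshold)
  res <- run_expression_simulation(X, labels, config$sim)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(res), file.path(outdir, "sim_result.json"),
                         auto_unbox = TRUE)
  }
  res
}

#' Sequentially optimize nu, tau, and Nmp on a dataset
#'
#' Builds an AUC oracle that re-runs discovery and simulation at the requested
#' (nu, tau, n_mp, seed) and applies the sequential optimization. Discovery is
#' cached per (nu) since tau and n_mp do not change the candidate scan.
#'
#' @inheritParams cmd_discover
#' @param policy a [repeat_policy()]
#' @param nmp_grid Nmp values for the final phase
#' @return result of [optimize_parameters()]
#' @export
cmd_optimize <- function(promoters, expr, config = run_config(),
                         policy = repeat_policy(base_seed = config$seed),
                         nmp_grid = c(1L, 2L, 3L, 5L, 10L),
                         outdir = NULL) {
  cache <- new.env(parent = emptyenv())
  auc_fun <- function(nu, tau, n_mp, seed) {
    key <- paste(nu, tau, sep = "_")
    if (is.null(cache[[key]])) {
      cfg <- config
      cfg$scoring <- scoring_params(nu = nu, tau = tau,
                                    a_hat = config$scoring$a_hat,
                                    highest_r_score = config$scoring$highest_r_score,
                                    down_policy = config$scoring$down_policy)
      disc <- cmd_discover(promoters, expr, cfg)
      groups <- c(disc$upstream$groups, disc$neartss$groups)
      groups <- groups[!duplicated(vapply(groups, `[[`, character(1), "seed"))]
      cache[[key]] <- list(disc = disc, pair_table = NULL, groups = groups)
    }
    st <- cache[[key]]
    cfg <- config
    cfg$n_mp <- n_mp
    cfg$sim$seed <- as.integer(seed)
    coloc <- NULL
    if (n_mp > 0L) {
      if (is.null(st$pair_table)) {        # pair scan is costly; do it lazily
        labels <- make_labels(expr, cfg$sim$up_threshold)
        up <- setNames(labels > 0, names(labels))
        st$pair_table <- evaluate_pairs(st$groups, promoters, up,
                                        cfg$pair_region)
        cache[[key]] <- st
      }
      sel <- select_enriched_pairs(st$pair_table, n_mp)
      coloc <- list(selection = sel, groups = st$groups)
    }
    res <- cmd_simulate(st$disc, promoters, expr, cfg, coloc = coloc)
    res$auc_roc
  }
  out <- optimize_parameters(auc_fun, policy, nmp_grid)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(nu = out$nu, tau = out$tau, n_mp = out$n_mp,
           aoar_nu = as.list(out$phases$nu$aoar),
           soar_tau = as.list(out$phases$tau$soar),
           aoar_nmp = as.list(out$phases$n_mp$aoar)),
      file.path(outdir, "optimization.json"), auto_unbox = TRUE)
    write_manifest(outdir, config, list(stage = "optimize"))
  }
  out
}
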