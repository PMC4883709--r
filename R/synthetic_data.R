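#' Specification of a planted motif
#'
#' @param motif DNA string to plant (possibly mutated per carrier)
#' @param carrier_fraction_up fraction of up-regulated genes carrying the motif
#' @param carrier_fraction_bg fraction of background genes carrying it
#' @param position_mode `"uniform"` (anywhere the motif fits), `"fixed"`
#'   (always at `offset`), or `"windowed"` (uniform within `window`)
#' @param offset TSS-relative offset of the motif's first base (fixed mode)
#' @param window `c(lo, hi)` TSS-relative window for the first base
#' @param per_base_mutation_prob probability that each planted base is
#'   replaced by a uniformly random different base
#' @param partner optional list(motif, separation_bp, jitter_bp): a second
#'   motif planted at `position(partner) = position(motif) + separation +
#'   U{-jitter..jitter}` in the same carriers
#' @return object of class `plant_spec`
#' @export
plant_spec <- function(motif, carrier_fraction_up = 0.8,
                       carrier_fraction_bg = 0.05,
                       position_mode = c("uniform", "fixed", "windowed"),
                       offset = NULL, window = NULL,
                       per_base_mutation_prob = 0,
                       partner = NULL) {
  position_mode <- match.arg(position_mode)
  if (grepl("[^ACGT]", motif)) stop("motif must be over {A,C,G,T}")
  if (carrier_fraction_up < 0 || carrier_fraction_up > 1 ||
      carrier_fraction_bg < 0 || carrier_fraction_bg > 1)
    stop("carrier fractions must be in [0, 1]")
  if (position_mode == "fixed" && is.null(offset)) stop("fixed mode needs offset")
  if (position_mode == "windowed" && is.null(window)) stop("windowed mode needs window")
  structure(list(motif = toupper(motif),
                 carrier_fraction_up = carrier_fraction_up,
                 carrier_fraction_bg = carrier_fraction_bg,
                 position_mode = position_mode, offset = offset,
                 window = if (is.null(window)) NULL else as.integer(window),
                 per_base_mutation_prob = per_base_mutation_prob,
                 partner = partner),
            class = "plant_spec")
}

#' Synthetic promoter/expression configuration
#'
#' Background promoters are i.i.d. over {A,C,G,T} with `base_probs`; `n_up`
#' genes receive up-regulation ratios uniform in `up_ratio_range`, the rest
#' log-normal around 1 with standard deviation `background_ratio_sigma` on the
#' log scale; each [plant_spec()] overwrites its (possibly mutated) motif at a
#' sampled position in its carrier genes.
#'
#' @param n_genes number of genes
#' @param region TSS-relative promoter window, default (-500, 150)
#' @param base_probs background probabilities of A, C, G, T (sum to 1)
#' @param n_up number of up-regulated genes
#' @param up_ratio_range `c(low, high)` for the up genes' ratios
#' @param background_ratio_sigma log-scale sd of background ratios
#' @param planted list of [plant_spec()]
#' @param seed integer seed
#' @return object of class `synth_config`
#' @export
synth_config <- function(n_genes, region = c(-500L, 150L),
                         base_probs = rep(0.25, 4), n_up = 0L,
                         up_ratio_range = c(3, 10),
                         background_ratio_sigma = 0.25,
                         planted = list(), seed = 1L) {
  if (abs(sum(base_probs) - 1) > 1e-9) stop("base_probs must sum to 1")
  if (n_up > n_genes) stop("n_up cannot exceed n_genes")
  if (region[1] >= region[2]) stop("region start must be < end")
  structure(list(n_genes = as.integer(n_genes), region = as.integer(region),
                 base_probs = base_probs, n_up = as.integer(n_up),
                 up_ratio_range = up_ratio_range,
                 background_ratio_sigma = background_ratio_sigma,
                 planted = planted, seed = as.integer(seed)),
            class = "synth_config")
}

sample_position <- function(spec, region, width, motif_len) {
  lo_all <- 0L; hi_all <- width - motif_len          # 0-based within sequence
  switch(spec$position_mode,
         fixed = spec$offset - region[1],
         uniform = sample.int(hi_all - lo_all + 1L, 1L) - 1L,
         windowed = {
           lo <- max(spec$window[1] - region[1], 0L)
           hi <- min(spec$window[2] - region[1] - motif_len, hi_all)
           if (hi < lo) stop("plant window cannot fit the motif")
           lo + sample.int(hi - lo + 1L, 1L) - 1L
         })
}

mutate_motif <- function(motif, p) {
  if (p <= 0) return(motif)
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    for (i in which(hit))
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic promoter set with planted motifs
#'
#' @param config a [synth_config()]
#' @return list(promoters, expr, truth) where `truth` is a data.frame of every
#'   insertion (gene_id, position TSS-relative, sequence inserted, motif,
#'   role = "primary"/"partner")
#' @export
generate_synthetic <- function(config) {
  set.seed(config$seed)
  region <- config$region
  width <- region[2] - region[1]
  n <- config$n_genes
  ids <- sprintf("g%04d", seq_len(n))
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(bases, width, replace = TRUE, prob = config$base_probs),
          collapse = ""), character(1))
  names(seqs) <- ids

  up_genes <- if (config$n_up > 0L) sample(ids, config$n_up) else character(0)
  ratios <- setNames(exp(rnorm(n, 0, config$background_ratio_sigma)), ids)
  if (length(up_genes) > 0L)
    ratios[up_genes] <- runif(length(up_genes),
                              config$up_ratio_range[1], config$up_ratio_range[2])

  occupied <- lapply(setNames(vector("list", n), ids), function(x) integer(0))
  truth <- list()
  insert_at <- function(gene, pos0, s, motif, role) {
    # pos0: 0-based start within the sequence
    span <- (pos0 + 1L):(pos0 + nchar(s))
    substr(seqs[gene], pos0 + 1L, pos0 + nchar(s)) <<- s
    occupied[[gene]] <<- c(occupied[[gene]], span)
    truth[[length(truth) + 1L]] <<- data.frame(
      gene_id = gene, position = region[1] + pos0, sequence = s,
      motif = motif, role = role, stringsAsFactors = FALSE)
  }
  free_at <- function(gene, pos0, len) {
    pos0 >= 0L && pos0 + len <= width &&
      !any((pos0 + 1L):(pos0 + len) %in% occupied[[gene]])
  }

  for (spec in config$planted) {
    mlen <- nchar(spec$motif)
    bg_genes <- setdiff(ids, up_genes)
    carriers <- c(
      if (length(up_genes) > 0L)
        sample(up_genes, round(spec$carrier_fraction_up * length(up_genes))),
      if (length(bg_genes) > 0L)
        sample(bg_genes, round(spec$carrier_fraction_bg * length(bg_genes))))
    for (g in carriers) {
      placed <- FALSE
      for (try in seq_len(100L)) {
        pos0 <- sample_position(spec, region, width, mlen)
        plen <- if (is.null(spec$partner)) 0L else nchar(spec$partner$motif)
        ppos0 <- NA_integer_
        if (!is.null(spec$partner)) {
          jit <- spec$partner$jitter_bp %||% 0L
          ppos0 <- pos0 + spec$partner$separation_bp +
            (if (jit > 0L) sample.int(2L * jit + 1L, 1L) - jit - 1L else 0L)
        }
        ok <- free_at(g, pos0, mlen) &&
          (is.null(spec$partner) ||
             (free_at(g, ppos0, plen) &&
                (ppos0 >= pos0 + mlen || ppos0 + plen <= pos0)))
        if (ok) {
          insert_at(g, pos0, mutate_motif(spec$motif,
                                          spec$per_base_mutation_prob),
                    spec$motif, "primary")
          if (!is.null(spec$partner))
            insert_at(g, ppos0,
                      mutate_motif(spec$partner$motif,
                                   spec$per_base_mutation_prob),
                      spec$partner$motif, "partner")
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place motif ", spec$motif, " in gene ", g,
             " after 100 attempts")
    }
  }

  truth_df <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(gene_id = character(0), position = integer(0),
               sequence = character(0), motif = character(0),
               role = character(0), stringsAsFactors = FALSE)
  list(promoters = promoter_set(seqs, region),
       expr = expression_table(ratios),
       truth = truth_df,
       up_genes = sort(up_genes))
}

#' Frozen benchmark scenarios
#'
#' Named configurations used by the acceptance suite:
#' * `"single_motif"` — 400 promoters over (-500, 150), 60 up-regulated genes
#'   (ratios uniform in 3..10), motif ACGTACGT planted without mutation in 80%
#'   of up-regulated and 5% of background genes, uniformly within (-500, 0).
#' * `"pair_coloc"` — as above plus a partner motif GATCCGGA planted 150 bp
#'   downstream of each ACGTACGT copy with +/-10 bp jitter, and an independent
#'   decoy motif TTGACCTA in 40% of up-regulated genes.
#' * `"null"` — no planting; ratios independent of sequence (60 up genes).
#'
#' @param name scenario name
#' @param seed integer seed
#' @return a [synth_config()]
#' @export
benchmark_scenario <- function(name = c("single_motif", "pair_coloc", "null"),
                               seed = 20130922L) {
  name <- match.arg(name)
  base <- list(n_genes = 400L, region = c(-500L, 150L), n_up = 60L,
               up_ratio_range = c(3, 10), background_ratio_sigma = 0.25,
               seed = seed)
  planted <- switch(
    name,
    null = list(),
    single_motif = list(
      plant_spec("ACGTACGT", carrier_fraction_up = 0.8,
                 carrier_fraction_bg = 0.05, position_mode = "windowed",
                 window = c(-500L, 0L))),
    pair_coloc = list(
      plant_spec("ACGTACGT", carrier_fraction_up = 0.7,
                 carrier_fraction_bg = 0.05, position_mode = "windowed",
                 window = c(-480L, -200L),
                 partner = list(motif = "GATCCGGA", separation_bp = 150L,
                                jitter_bp = 10L)),
      plant_spec("TTGACCTA", carrier_fraction_up = 0.4,
                 carrier_fraction_bg = 0.05, position_mode = "windowed",
                 window = c(-500L, 0L))))
  do.call(synth_config, c(base, list(planted = planted)))
}

#' Write a synthetic dataset to disk (FASTA + expression TSV + truth JSON)
#' @param data list from [generate_synthetic()]
#' @param outdir output directory (created if needed)
#' @export
write_synthetic <- function(data, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(data$promoters$sequences, file.path(outdir, "promoters.fasta"))
  write_expression_table(data$expr, file.path(outdir, "expression.tsv"))
  jsonlite::write_json(
    list(region = data$promoters$region, truth = data$truth,
         up_genes = data$up_genes),
    file.path(outdir, "truth.json"))
  invisible(outdir)
}
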