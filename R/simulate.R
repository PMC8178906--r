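# Synthetic cohort generator. Emits an annotated snoRNA cohort (annotation
# TSV, FASTA, GTF host models, bedGraph conservation, BED SNPs, a
# replicate-structured TPM matrix and a sample map) together with the planted
# ground truth, emulating the statistical structure of a multi-tissue snoRNA
# family study: heavy-tailed family sizes with many singletons, roughly
# 35-40% expressed members, log-normal abundance spanning several orders of
# magnitude, multiplicative replicate noise, planted top-member switches,
# class-specific host placement and member sequences mutated from a family
# ancestor.
#
# Replicate noise is clamped log-normal, so every planted status, top call
# and switch is recoverable by a strict deterministic margin: all dominance
# gaps are sized above the worst-case ratio of two clamped noise factors.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a 7-tissue, 3-replicate cohort of 200 box C/D and 100
#' box H/ACA families with heavy-tailed family sizes (many singletons, a few
#' very large families), class-specific expressed
#' fractions (singletons almost always expressed), 18 + 9 planted top-member
#' switches at 4-fold effect, 20% replicate noise CV, 8 + 5 families with a
#' planted identical pair, concentrated single-host placement for C/D versus
#' dispersed hosts for H/ACA, and intronic distances peaking near 70 nt for
#' C/D snoRNAs.
#'
#' @param seed Integer seed; mandatory.
#' @param n_cd_families,n_haca_families Family counts per class.
#' @param tissues Tissue labels (canonical order).
#' @param replicates_per_tissue Samples per tissue.
#' @param p_expressed Named per-class overall expressed fraction targeted.
#'   Singletons are expressed with `p_expressed_singleton`; the multi-member
#'   rate is derived so the class-wide expectation equals `p_expressed`.
#' @param p_expressed_singleton Probability that a singleton is expressed.
#' @param family_size Per-class family-size mixture: `p_singleton`,
#'   negative-binomial `nb_mu`/`nb_size` for multi-member sizes (offset by
#'   2), and `p_large`/`large_range` for occasional very large families.
#' @param threshold Expression threshold in TPM.
#' @param abundance Log10-normal parameters for expressed-member base TPM
#'   (`meanlog10`, `sdlog10`) and clamps (`min_tpm`, `max_tpm`).
#' @param replicate_noise_cv Replicate noise CV, percent.
#' @param noise_trunc Clamp for the noise z-score (in sd units).
#' @param n_switch_families Named per-class number of planted switches.
#' @param switch_effect Fold-change by which the block owner dominates.
#' @param tissue_effect Fold boost of each member's designated top tissue.
#' @param p_coherent_top Per-class probability that a non-switch family's
#'   expressed members all share one top tissue.
#' @param host_strategy Per-class list: `p_same_host` (all copies in one host
#'   gene), `p_intergenic_family` (family entirely intergenic),
#'   `p_intergenic_member` (per-member intergenic rate in multi-host
#'   families), `p_coding` (coding vs noncoding host biotype).
#' @param sequence_model Per-class ancestor length range and per-copy
#'   per-site `mutation_rate`.
#' @param n_identical_pairs Named per-class number of families given one
#'   planted identical member pair.
#' @param conservation_model Mean conservation for expressed vs unexpressed
#'   members and the Beta concentration.
#' @param snp_model SNP rate per nucleotide and the factor by which the rate
#'   is scaled down for conserved (expressed) members.
#' @param intron_distance Per-class log-normal parameters for the distance
#'   from the snoRNA 3' end to the downstream exon.
#' @return A validated `snofam_config` list.
#' @export
synthetic_config <- function(
    seed,
    n_cd_families = 200, n_haca_families = 100,
    tissues = c("brain", "liver", "prostate", "breast", "ovary", "testis",
                "skeletal_muscle"),
    replicates_per_tissue = 3,
    p_expressed = c(CD = 0.373, HACA = 0.410),
    p_expressed_singleton = 0.96,
    family_size = list(
      CD = list(p_singleton = 0.40, nb_mu = 4, nb_size = 1.2,
                p_large = 0.02, large_range = c(100, 450)),
      HACA = list(p_singleton = 0.29, nb_mu = 3.5, nb_size = 1.5,
                  p_large = 0.02, large_range = c(20, 39))),
    threshold = 1,
    abundance = list(meanlog10 = 1.5, sdlog10 = 1.0, min_tpm = 2,
                     max_tpm = 5e4),
    replicate_noise_cv = 20, noise_trunc = 2.5,
    n_switch_families = c(CD = 18, HACA = 9),
    switch_effect = 4, tissue_effect = 3,
    p_coherent_top = c(CD = 0.29, HACA = 0.15),
    host_strategy = list(
      CD = list(p_same_host = 0.6, p_intergenic_family = 2 / 126,
                p_intergenic_member = 0.05, p_coding = 0.75),
      HACA = list(p_same_host = 0.1, p_intergenic_family = 14 / 91,
                  p_intergenic_member = 0.05, p_coding = 0.75)),
    sequence_model = list(length_range = list(CD = c(70, 130),
                                              HACA = c(110, 145)),
                          mutation_rate = 0.08),
    n_identical_pairs = c(CD = 8, HACA = 5),
    conservation_model = list(expressed_mean = 0.7, unexpressed_mean = 0.2,
                              concentration = 10),
    snp_model = list(rate_per_nt = 0.01, conserved_scale = 0.3),
    intron_distance = list(CD = list(meanlog = log(70), sdlog = 0.6),
                           HACA = list(meanlog = log(300), sdlog = 1.0))) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- list(
    seed = as.integer(seed), n_cd_families = n_cd_families,
    n_haca_families = n_haca_families, tissues = tissues,
    replicates_per_tissue = replicates_per_tissue,
    p_expressed = p_expressed,
    p_expressed_singleton = p_expressed_singleton,
    family_size = family_size, threshold = threshold,
    abundance = abundance, replicate_noise_cv = replicate_noise_cv,
    noise_trunc = noise_trunc, n_switch_families = n_switch_families,
    switch_effect = switch_effect, tissue_effect = tissue_effect,
    p_coherent_top = p_coherent_top, host_strategy = host_strategy,
    sequence_model = sequence_model,
    n_identical_pairs = n_identical_pairs,
    conservation_model = conservation_model, snp_model = snp_model,
    intron_distance = intron_distance
  )
  probs <- c(p_expressed, p_expressed_singleton, p_coherent_top,
             unlist(lapply(host_strategy, function(h)
               c(h$p_same_host, h$p_intergenic_family,
                 h$p_intergenic_member, h$p_coding))),
             sequence_model$mutation_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (switch_effect < 1) stop("switch_effect must be >= 1", call. = FALSE)
  if (any(c(n_cd_families, n_haca_families, n_switch_families,
            n_identical_pairs) < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  # worst-case ratio of two clamped replicate-noise factors; planted truth
  # is only guaranteed recoverable when the planted fold-changes beat it
  sdlog <- sqrt(log(1 + (replicate_noise_cv / 100)^2))
  cfg$noise_margin <- exp(2 * noise_trunc * sdlog)
  if (sum(n_switch_families) > 0 && switch_effect <= cfg$noise_margin) {
    warning("switch_effect does not exceed the worst-case noise ratio (",
            signif(cfg$noise_margin, 3),
            "); planted switches may not be exactly recoverable")
  }
  structure(cfg, class = "snofam_config")
}

# Heavy-tailed family sizes: a singleton spike, negative-binomial
# multi-member sizes, and a small probability of a very large family.
sample_family_sizes <- function(n, p) {
  kind <- runif(n)
  sizes <- integer(n)
  singleton <- kind < p$p_singleton
  large <- !singleton & kind < p$p_singleton + p$p_large
  mid <- !singleton & !large
  sizes[singleton] <- 1L
  sizes[large] <- sample(seq(p$large_range[1], p$large_range[2]),
                         sum(large), replace = TRUE)
  sizes[mid] <- pmin(2L + stats::rnbinom(sum(mid), mu = p$nb_mu,
                                         size = p$nb_size),
                     p$large_range[1] - 1L)
  sizes
}

#' Plant a top-member switch across tissue blocks
#'
#' Partitions the tissue panel into as many contiguous blocks as there are
#' switching members and returns per-member tissue multipliers: each member
#' dominates its own block by `effect` fold (before noise), with the first
#' tissue of the block further boosted by `top_boost` so the member's top
#' tissue is unambiguous.
#'
#' @param member_ids Ids of the switching members (>= 2, at most one per
#'   tissue).
#' @param tissues Tissue labels.
#' @param effect Fold-change of block dominance; must exceed 1.
#' @param top_boost Extra fold boost of each block's designated top tissue.
#' @return List with the `multipliers` matrix (member x tissue), the planted
#'   `top_tissue` per member and the `blocks` partition.
#' @export
plant_switch <- function(member_ids, tissues, effect, top_boost = 3) {
  if (effect <= 1) {
    stop("switch effect must exceed 1 (degenerate switch)", call. = FALSE)
  }
  n <- length(member_ids)
  if (n < 2) stop("need at least 2 members to plant a switch", call. = FALSE)
  if (n > length(tissues)) {
    stop("more switching members than tissues", call. = FALSE)
  }
  cuts <- sort(sample(seq(2, length(tissues)), n - 1))
  starts <- c(1, cuts)
  ends <- c(cuts - 1, length(tissues))
  mult <- matrix(1, n, length(tissues),
                 dimnames = list(member_ids, tissues))
  top <- character(n)
  for (i in seq_len(n)) {
    block <- seq(starts[i], ends[i])
    mult[i, block] <- effect
    mult[i, block[1]] <- effect * top_boost
    top[i] <- tissues[block[1]]
  }
  list(multipliers = mult,
       top_tissue = setNames(top, member_ids),
       blocks = Map(function(s, e) tissues[s:e], starts, ends))
}

#' Simulate a synthetic snoRNA cohort with planted ground truth
#'
#' Runs the full generator under the configured seed. The same seed yields an
#' identical cohort; [write_bundle()] then yields a byte-identical file
#' bundle. Raises an error before any generation output if the configuration
#' is infeasible (more planted switches or identical pairs than families can
#' carry).
#'
#' @param config A `snofam_config` from [synthetic_config()].
#' @return A `snofam_sim` list: `records` (annotation tibble), `abundance`,
#'   `panel`, `gtf_lines`, `conservation`, `snps`, `truth_sno`,
#'   `truth_family`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "snofam_config"))
  withr::with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(cfg) {
  tissues <- cfg$tissues
  n_rep <- cfg$replicates_per_tissue
  panel <- tibble::tibble(
    sample_id = paste0(rep(tissues, each = n_rep), "_",
                       rep(seq_len(n_rep), length(tissues))),
    tissue = rep(tissues, each = n_rep)
  )

  # --- family skeleton ------------------------------------------------------
  fam <- dplyr::bind_rows(
    tibble::tibble(
      box_type = "CD",
      family_id = sprintf("FAMCD%04d", seq_len(cfg$n_cd_families)),
      size = sample_family_sizes(cfg$n_cd_families, cfg$family_size$CD)),
    tibble::tibble(
      box_type = "HACA",
      family_id = sprintf("FAMHA%04d", seq_len(cfg$n_haca_families)),
      size = sample_family_sizes(cfg$n_haca_families,
                                 cfg$family_size$HACA))
  )

  members <- fam |>
    dplyr::rowwise() |>
    dplyr::reframe(box_type = .data$box_type, family_id = .data$family_id,
                   size = .data$size,
                   snorna_id = sprintf("%s.M%03d", .data$family_id,
                                       seq_len(.data$size)))
  n_mem <- nrow(members)

  # --- expression statuses and base abundance -------------------------------
  # p_expressed is the per-class overall target; singletons are almost
  # always expressed, so the multi-member rate is derived to hit the target
  # given the realized singleton share
  p_multi <- c(CD = NA_real_, HACA = NA_real_)
  for (cls in c("CD", "HACA")) {
    in_cls <- members$box_type == cls
    n_c <- sum(in_cls)
    s_c <- sum(in_cls & members$size == 1)
    p_multi[[cls]] <- if (n_c == s_c) cfg$p_expressed[[cls]] else
      min(1, max(0, (cfg$p_expressed[[cls]] * n_c -
                       s_c * cfg$p_expressed_singleton) / (n_c - s_c)))
  }
  p <- ifelse(members$size == 1, cfg$p_expressed_singleton,
              p_multi[members$box_type])
  members$expressed <- runif(n_mem) < p
  base <- rep(NA_real_, n_mem)
  n_exp <- sum(members$expressed)
  base[members$expressed] <- pmin(
    pmax(10^rnorm(n_exp, cfg$abundance$meanlog10, cfg$abundance$sdlog10),
         cfg$abundance$min_tpm), cfg$abundance$max_tpm)
  members$base <- base

  fam_exp <- members |>
    dplyr::group_by(.data$family_id, .data$box_type) |>
    dplyr::summarise(n_expressed = sum(.data$expressed), .groups = "drop")

  # feasibility before any output is assembled
  switch_ids <- character()
  for (cls in c("CD", "HACA")) {
    eligible <- fam_exp$family_id[fam_exp$box_type == cls &
                                    fam_exp$n_expressed >= 2]
    want <- cfg$n_switch_families[[cls]]
    if (want > length(eligible)) {
      stop(sprintf(
        "infeasible config: %d planted %s switches requested but only %d families have >= 2 expressed members",
        want, cls, length(eligible)), call. = FALSE)
    }
    if (want > 0) switch_ids <- c(switch_ids, sample(eligible, want))
  }
  for (cls in c("CD", "HACA")) {
    multi <- fam$family_id[fam$box_type == cls & fam$size >= 2]
    if (cfg$n_identical_pairs[[cls]] > length(multi)) {
      stop(sprintf(
        "infeasible config: %d planted identical pairs requested for %s but only %d families have >= 2 members",
        cfg$n_identical_pairs[[cls]], cls, length(multi)), call. = FALSE)
    }
  }

  # dominance gaps sized above the worst-case clamped-noise ratio so planted
  # ranks survive replicate noise exactly
  margin <- cfg$noise_margin
  rank_gap <- cfg$tissue_effect * margin * 1.1
  scale_div <- max(1.5, cfg$tissue_effect * margin / cfg$switch_effect * 1.1)

  # --- per-family tissue profiles -------------------------------------------
  mult <- matrix(1, n_mem, length(tissues),
                 dimnames = list(members$snorna_id, tissues))
  members$top_tissue <- NA_character_
  fam_truth <- list()

  for (fid in fam$family_id) {
    idx <- which(members$family_id == fid)
    cls <- members$box_type[idx[1]]
    eidx <- idx[members$expressed[idx]]
    is_switch <- fid %in% switch_ids
    n_top <- 0L
    if (is_switch) {
      n_want <- min(length(eidx), sample(2:3, 1),
                    length(tissues))
      owners <- eidx[order(-members$base[eidx])][seq_len(n_want)]
      m <- max(members$base[owners])
      members$base[owners] <- m
      others <- setdiff(eidx, owners)
      if (length(others) > 0) {
        members$base[others] <- pmin(members$base[others], m / scale_div)
        for (j in others) {
          t <- sample(tissues, 1)
          mult[j, t] <- cfg$tissue_effect
          members$top_tissue[j] <- t
        }
      }
      planted <- plant_switch(members$snorna_id[owners], tissues,
                              cfg$switch_effect, cfg$tissue_effect)
      mult[owners, ] <- planted$multipliers
      members$top_tissue[owners] <- unname(planted$top_tissue)
      n_top <- n_want
    } else if (length(eidx) > 0) {
      coherent <- runif(1) < cfg$p_coherent_top[[cls]]
      tops <- if (coherent) rep(sample(tissues, 1), length(eidx)) else
        sample(tissues, length(eidx), replace = TRUE)
      for (k in seq_along(eidx)) {
        mult[eidx[k], tops[k]] <- cfg$tissue_effect
        members$top_tissue[eidx[k]] <- tops[k]
      }
      if (length(eidx) >= 2) {
        ord <- eidx[order(-members$base[eidx])]
        if (members$base[ord[1]] < rank_gap * members$base[ord[2]]) {
          members$base[ord[1]] <- rank_gap * members$base[ord[2]]
        }
      }
      n_top <- if (length(eidx) >= 1) 1L else 0L
    }
    fam_truth[[fid]] <- tibble::tibble(
      family_id = fid, switch = is_switch,
      n_top_members = if (length(eidx) >= 2) as.integer(n_top) else
        min(1L, length(eidx)))
  }

  # --- abundance matrix -----------------------------------------------------
  sdlog <- sqrt(log(1 + (cfg$replicate_noise_cv / 100)^2))
  tissue_of <- panel$tissue
  n_s <- nrow(panel)
  vals <- matrix(0, n_mem, n_s, dimnames = list(members$snorna_id,
                                                panel$sample_id))
  eps <- matrix(pmin(pmax(rnorm(n_mem * n_s), -cfg$noise_trunc),
                     cfg$noise_trunc), n_mem, n_s)
  mean_mat <- members$base * mult[, tissue_of, drop = FALSE]
  expressed_rows <- which(members$expressed)
  vals[expressed_rows, ] <- mean_mat[expressed_rows, , drop = FALSE] *
    exp(eps[expressed_rows, , drop = FALSE] * sdlog)
  unexpr <- which(!members$expressed)
  vals[unexpr, ] <- matrix(runif(length(unexpr) * n_s, 0,
                                 0.5 * cfg$threshold),
                           length(unexpr), n_s)
  vals <- signif(vals, 6)
  abundance <- dplyr::bind_cols(
    tibble::tibble(snorna_id = members$snorna_id),
    tibble::as_tibble(vals))

  # --- sequences ------------------------------------------------------------
  bases4 <- c("A", "C", "G", "T")
  mutate_seq <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    hit <- runif(length(v)) < rate
    if (any(hit)) {
      v[hit] <- vapply(v[hit], function(b)
        sample(setdiff(bases4, b), 1), character(1))
    }
    paste(v, collapse = "")
  }
  members$sequence <- NA_character_
  planted_identical <- character()
  for (cls in c("CD", "HACA")) {
    multi <- fam$family_id[fam$box_type == cls & fam$size >= 2]
    k <- cfg$n_identical_pairs[[cls]]
    if (k > 0) planted_identical <- c(planted_identical, sample(multi, k))
  }
  for (fid in fam$family_id) {
    idx <- which(members$family_id == fid)
    cls <- members$box_type[idx[1]]
    rng <- cfg$sequence_model$length_range[[cls]]
    len <- sample(seq(rng[1], rng[2]), 1)
    ancestor <- paste(sample(bases4, len, replace = TRUE), collapse = "")
    seqs <- vapply(idx, function(i)
      mutate_seq(ancestor, cfg$sequence_model$mutation_rate), character(1))
    if (fid %in% planted_identical) seqs[2] <- seqs[1]
    # break accidental identities so the identical-pair truth stays exact
    for (j in seq_along(seqs)) {
      guard <- 0
      while (any(seqs[seq_len(j - 1)] == seqs[j]) &&
             !(fid %in% planted_identical && j == 2) && guard < 50) {
        pos <- sample(nchar(seqs[j]), 1)
        old <- substr(seqs[j], pos, pos)
        substr(seqs[j], pos, pos) <- sample(setdiff(bases4, old), 1)
        guard <- guard + 1
      }
    }
    members$sequence[idx] <- seqs
  }

  # --- host placement and genome layout -------------------------------------
  members$host_gene_id <- NA_character_
  members$host_biotype <- "intergenic"
  members$chrom <- "chrS"
  members$start <- NA_integer_
  members$end <- NA_integer_
  members$strand <- "+"
  members$intron_distance <- NA_real_

  gtf <- character()
  gene_counter <- 0L
  cursor <- 1000L
  chrom <- "chrS"

  draw_distance <- function(cls) {
    p <- cfg$intron_distance[[cls]]
    max(10L, as.integer(round(rlnorm(1, p$meanlog, p$sdlog))))
  }

  # Lays out one host gene containing the given members (one intron each) and
  # returns GTF lines; assigns coordinates and planted distances in place.
  emit_gene <- function(midx, biotype) {
    gene_counter <<- gene_counter + 1L
    gid <- sprintf("G%04d", gene_counter)
    cls <- members$box_type[midx[1]]
    strand <- sample(c("+", "-"), 1)
    exon_w <- 120L
    pad <- 150L
    k <- length(midx)
    d <- vapply(midx, function(i) draw_distance(cls), integer(1))
    lens <- nchar(members$sequence[midx])

    # transcript-orientation segment layout
    exons <- list(c(0L, exon_w))
    snos <- list()
    cur <- exon_w
    for (j in seq_len(k)) {
      cur <- cur + pad
      snos[[j]] <- c(cur, cur + lens[j])
      cur <- cur + lens[j] + d[j]
      exons[[j + 1]] <- c(cur, cur + exon_w)
      cur <- cur + exon_w
    }
    lg <- cur
    gstart <- cursor

    to_abs <- function(seg) {
      if (strand == "+") c(gstart + seg[1], gstart + seg[2])
      else c(gstart + lg - seg[2], gstart + lg - seg[1])
    }

    for (j in seq_len(k)) {
      ab <- to_abs(snos[[j]])
      members$start[midx[j]] <<- ab[1]
      members$end[midx[j]] <<- ab[2]
      members$strand[midx[j]] <<- strand
      members$host_gene_id[midx[j]] <<- gid
      members$host_biotype[midx[j]] <<- biotype
      members$intron_distance[midx[j]] <<- d[j]
    }

    gbt <- if (biotype == "coding") "protein_coding" else "lncRNA"
    tx_defs <- list(list(name = "t1", exons = exons))
    if (runif(1) < 0.4) {
      tx_defs <- c(tx_defs, list(list(name = "t0",
                                      exons = list(c(0L, lg)))))
    }
    if (runif(1) < 0.3) {
      tx_defs <- c(tx_defs, list(list(name = "t1b", exons = exons)))
    }
    if (runif(1) < 0.3) {
      # isoform with an extra exon overlapping the first snoRNA: most exons,
      # sorted first, skipped for that snoRNA by the assignment rule
      extra <- c(snos[[1]][1] - 60L, snos[[1]][1] + 20L)
      tx_defs <- c(tx_defs, list(list(name = "t2",
                                      exons = c(exons[1], list(extra),
                                                exons[-1]))))
    }

    lines <- sprintf(
      '%s\tsnofam\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
      chrom, gstart + 1L, gstart + lg, strand, gid, gbt)
    for (tx in tx_defs) {
      tid <- sprintf("%s.%s", gid, tx$name)
      lines <- c(lines, sprintf(
        '%s\tsnofam\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_name "%s"; gene_biotype "%s";',
        chrom, gstart + 1L, gstart + lg, strand, gid, tid, tx$name, gbt))
      for (seg in tx$exons) {
        ab <- to_abs(seg)
        lines <- c(lines, sprintf(
          '%s\tsnofam\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_name "%s"; gene_biotype "%s";',
          chrom, ab[1] + 1L, ab[2], strand, gid, tid, tx$name, gbt))
      }
    }
    cursor <<- gstart + lg + 500L
    lines
  }

  for (fid in fam$family_id) {
    idx <- which(members$family_id == fid)
    cls <- members$box_type[idx[1]]
    hs <- cfg$host_strategy[[cls]]
    if (runif(1) < hs$p_intergenic_family) {
      for (i in idx) {
        members$start[i] <- cursor + 100L
        members$end[i] <- cursor + 100L + nchar(members$sequence[i])
        members$strand[i] <- sample(c("+", "-"), 1)
        cursor <- members$end[i] + 600L
      }
    } else if (runif(1) < hs$p_same_host) {
      biotype <- if (runif(1) < hs$p_coding) "coding" else "noncoding"
      gtf <- c(gtf, emit_gene(idx, biotype))
    } else {
      for (i in idx) {
        if (runif(1) < hs$p_intergenic_member) {
          members$start[i] <- cursor + 100L
          members$end[i] <- cursor + 100L + nchar(members$sequence[i])
          members$strand[i] <- sample(c("+", "-"), 1)
          cursor <- members$end[i] + 600L
        } else {
          biotype <- if (runif(1) < hs$p_coding) "coding" else "noncoding"
          gtf <- c(gtf, emit_gene(i, biotype))
        }
      }
    }
  }

  # --- conservation track and SNPs ------------------------------------------
  cm <- cfg$conservation_model
  cons_mean <- ifelse(members$expressed, cm$expressed_mean,
                      cm$unexpressed_mean)
  score <- round(rbeta(n_mem, cons_mean * cm$concentration,
                       (1 - cons_mean) * cm$concentration), 3)
  cons_rows <- list()
  for (i in seq_len(n_mem)) {
    s <- members$start[i]
    e <- members$end[i]
    if (runif(1) < 0.3 && e - s > 20) {
      cut <- s + sample(seq(5L, e - s - 5L), 1)
      cons_rows[[i]] <- tibble::tibble(chrom = members$chrom[i],
                                       start = c(s, cut), end = c(cut, e),
                                       score = score[i])
    } else {
      cons_rows[[i]] <- tibble::tibble(chrom = members$chrom[i],
                                       start = s, end = e, score = score[i])
    }
  }
  conservation <- dplyr::bind_rows(cons_rows) |>
    dplyr::arrange(.data$chrom, .data$start)

  snp_rate <- cfg$snp_model$rate_per_nt *
    ifelse(members$expressed, cfg$snp_model$conserved_scale, 1)
  snp_rows <- list()
  for (i in seq_len(n_mem)) {
    len <- members$end[i] - members$start[i]
    n_snp <- rbinom(1, len, snp_rate[i])
    if (n_snp > 0) {
      pos <- members$start[i] + sort(sample.int(len, n_snp)) - 1L
      snp_rows[[length(snp_rows) + 1]] <-
        tibble::tibble(chrom = members$chrom[i], pos = pos)
    }
  }
  snps <- if (length(snp_rows) > 0) {
    dplyr::bind_rows(snp_rows) |> dplyr::arrange(.data$chrom, .data$pos)
  } else tibble::tibble(chrom = character(), pos = integer())

  # --- assemble outputs and truth -------------------------------------------
  records <- tibble::tibble(
    snorna_id = members$snorna_id, name = members$snorna_id,
    box_type = members$box_type, family_id = members$family_id,
    sequence = members$sequence, chrom = members$chrom,
    start = as.integer(members$start), end = as.integer(members$end),
    strand = members$strand, host_gene_id = members$host_gene_id,
    host_biotype = members$host_biotype
  )

  truth_sno <- tibble::tibble(
    snorna_id = members$snorna_id,
    expressed = members$expressed,
    top_tissue = members$top_tissue,
    intron_distance = members$intron_distance,
    context = members$host_biotype
  )

  fam_flags <- dplyr::bind_rows(fam_truth)
  truth_family <- members |>
    dplyr::group_by(.data$family_id, .data$box_type) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_expressed = sum(.data$expressed),
      context_all = context_category(.data$host_biotype),
      context_expressed = context_category(
        .data$host_biotype[.data$expressed]),
      same_host = {
        hosts <- .data$host_gene_id[.data$expressed]
        if (sum(.data$expressed) < 2) NA
        else !anyNA(hosts) && length(unique(hosts)) == 1
      },
      .groups = "drop"
    ) |>
    dplyr::left_join(fam_flags, by = "family_id") |>
    dplyr::mutate(
      identical_pair = .data$family_id %in% planted_identical) |>
    dplyr::arrange(.data$family_id)

  structure(
    list(records = records, abundance = abundance, panel = panel,
         gtf_lines = gtf, conservation = conservation, snps = snps,
         truth_sno = truth_sno, truth_family = truth_family,
         config = cfg),
    class = "snofam_sim"
  )
}

#' @export
print.snofam_sim <- function(x, ...) {
  cat(sprintf(
    "<snofam_sim> seed %d: %d snoRNAs in %d families, %d samples (%d tissues)\n",
    x$config$seed, nrow(x$records), nrow(x$truth_family), nrow(x$panel),
    length(x$config$tissues)))
  invisible(x)
}

#' Write a simulated cohort to a file bundle
#'
#' Emits `annotation.tsv`, `abundance.tsv`, `samples.tsv`, `hosts.gtf`,
#' `conservation.bedgraph`, `snps.bed`, `sequences.fa`, `truth_sno.tsv`,
#' `truth_family.tsv` and `config.yaml`. Output is byte-identical for
#' identical simulations.
#'
#' @param sim A `snofam_sim` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of paths, invisibly.
#' @export
write_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "snofam_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    annotation = file.path(dir, "annotation.tsv"),
    abundance = file.path(dir, "abundance.tsv"),
    samples = file.path(dir, "samples.tsv"),
    gtf = file.path(dir, "hosts.gtf"),
    conservation = file.path(dir, "conservation.bedgraph"),
    snps = file.path(dir, "snps.bed"),
    fasta = file.path(dir, "sequences.fa"),
    truth_sno = file.path(dir, "truth_sno.tsv"),
    truth_family = file.path(dir, "truth_family.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_annotation(sim$records, paths[["annotation"]])
  write_abundance(sim$abundance, paths[["abundance"]])
  write_sample_panel(sim$panel, paths[["samples"]])
  writeLines(sim$gtf_lines, paths[["gtf"]])
  write_bedgraph(sim$conservation, paths[["conservation"]])
  write_bed(sim$snps, paths[["snps"]])
  write_fasta(sim$records, paths[["fasta"]])
  readr::write_tsv(sim$truth_sno, paths[["truth_sno"]], progress = FALSE)
  readr::write_tsv(sim$truth_family, paths[["truth_family"]],
                   progress = FALSE)
  cfg <- sim$config
  cfg$noise_margin <- NULL
  yaml::write_yaml(unclass(cfg), paths[["config"]])
  invisible(paths)
}
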