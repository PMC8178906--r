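# End-to-end orchestration: ingest -> tissue means -> expression -> identity
# -> genomics -> variability -> switches -> per-snoRNA and per-family
# summary tables plus a per-class statistics report.

read_if_path <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1) reader(x, ...) else x
}

#' Run the full snoRNA family pipeline
#'
#' Consumes an annotation table, a TPM abundance matrix and a sample map
#' (paths or tibbles), plus optional genomic inputs (GTF host model,
#' bedGraph conservation track, BED SNP sites), and produces the per-snoRNA
#' summary, the per-family summary and a per-class statistics report.
#' Columns depending on an absent optional input are emitted as `NA`, never
#' silently zero. Stage errors abort with the stage name and cause.
#'
#' @param annotation Annotation TSV path or tibble ([read_annotation()]).
#' @param abundance Abundance TSV path or tibble ([read_abundance()]).
#' @param samples Sample map TSV path or panel tibble.
#' @param gtf Optional GTF path or `host_model`.
#' @param conservation Optional bedGraph path or conservation tibble.
#' @param snps Optional BED path or SNP tibble.
#' @param threshold,inclusive Expression rule (see [is_expressed()]).
#' @param ddof CV degrees-of-freedom convention (see [cv_percent()]).
#' @param cor_method Correlation method for [correlate_size_abundance()].
#' @param identity Compute pairwise identity columns (can be disabled for
#'   speed).
#' @param quiet Suppress per-stage logging.
#' @return A `snofam_result`: list with tibbles `sno_summary` and
#'   `family_summary`, the nested `report` list, the [switch_table()]
#'   `switches`, and `params`.
#' @export
run_pipeline <- function(annotation, abundance, samples, gtf = NULL,
                         conservation = NULL, snps = NULL, threshold = 1,
                         inclusive = TRUE, ddof = 1,
                         cor_method = c("pearson", "spearman"),
                         identity = TRUE, quiet = TRUE) {
  cor_method <- match.arg(cor_method)
  log_stage <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  records <- stage("ingest", read_if_path(annotation, read_annotation))
  panel <- stage("ingest", read_if_path(samples, read_sample_panel))
  mat <- stage("ingest", {
    m <- read_if_path(abundance, read_abundance, panel = panel)
    validate_abundance(m, panel)
    m
  })
  host <- if (!is.null(gtf)) stage("ingest", read_if_path(gtf, read_gtf))
  track <- if (!is.null(conservation)) {
    stage("ingest", read_if_path(conservation, read_bedgraph))
  }
  sites <- if (!is.null(snps)) stage("ingest", read_if_path(snps, read_bed))
  log_stage("ingest", sprintf("%d snoRNAs, %d samples", nrow(records),
                              nrow(panel)))

  means <- stage("tissue_means", tissue_means(mat, panel))
  statuses <- stage("expression",
                    expression_table(mat, panel, threshold, inclusive))
  log_stage("expression", sprintf("%d expressed", sum(statuses$expressed)))

  ident <- if (identity) stage("identity", mean_member_identity(records))
  else tibble::tibble(snorna_id = records$snorna_id,
                      alignment_score = NA_real_)
  identical_fams <- if (identity) stage("identity",
                                        find_identical_pairs(records))
  else tibble::tibble(family_id = character(),
                      n_identical_pairs = integer())

  cons <- if (!is.null(track)) {
    stage("genomics", conservation_score(records, track))
  } else tibble::tibble(snorna_id = records$snorna_id,
                        conservation_score = NA_real_)
  dens <- if (!is.null(sites)) stage("genomics", snp_density(records, sites))
  else tibble::tibble(snorna_id = records$snorna_id, n_snps = NA_integer_,
                      snp_per_nt_1000 = NA_real_)
  placement <- if (!is.null(host)) {
    stage("genomics", assign_host_transcript(records, host))
  } else tibble::tibble(snorna_id = records$snorna_id,
                        transcript_id = NA_character_, intronic = NA,
                        distance_to_downstream_exon = NA_real_)
  ctx_all <- stage("genomics",
                   classify_family_context(records, statuses, FALSE))
  ctx_exp <- stage("genomics",
                   classify_family_context(records, statuses, TRUE))

  tissues <- tissue_cols(means)
  sno_cv <- stage("variability", tibble::tibble(
    snorna_id = means$snorna_id,
    cv = apply(as.matrix(means[, tissues, drop = FALSE]), 1, function(x) {
      if (mean(x) == 0) NA_real_ else cv_percent(x, ddof)
    })
  ))
  fam_var <- stage("variability",
                   family_variability(records, means, statuses, ddof))
  fam_tot <- stage("variability",
                   family_total_abundance(records, mat, statuses))
  cors <- stage("variability", correlate_size_abundance(
    records, mat, statuses, method = cor_method))

  st <- stage("switches", switch_table(records, means, statuses))
  same_top <- stage("switches", same_tissue_top_fraction(records, statuses))
  log_stage("switches", sprintf("%d switch families", sum(st$switch)))

  sno_summary <- records |>
    dplyr::select("snorna_id", "name", "box_type", "family_id",
                  "host_gene_id", "host_biotype") |>
    dplyr::rename(genomic_context = "host_biotype") |>
    dplyr::left_join(statuses, by = "snorna_id") |>
    dplyr::left_join(sno_cv, by = "snorna_id") |>
    dplyr::left_join(ident, by = "snorna_id") |>
    dplyr::left_join(cons, by = "snorna_id") |>
    dplyr::left_join(dens[, c("snorna_id", "snp_per_nt_1000")],
                     by = "snorna_id") |>
    dplyr::left_join(placement[, c("snorna_id", "intronic",
                                   "distance_to_downstream_exon")],
                     by = "snorna_id")

  fam_members <- family_expression_summary(records, statuses)
  family_summary <- fam_members |>
    dplyr::left_join(fam_tot[, c("family_id", "average_sum_tpm")],
                     by = "family_id") |>
    dplyr::left_join(st[, c("family_id", "eligible", "switch",
                            "n_top_members")], by = "family_id") |>
    dplyr::left_join(fam_var[, c("family_id", "family_cv", "mean_member_cv",
                                 "diag_distance")], by = "family_id") |>
    dplyr::left_join(ctx_all[, c("family_id", "category", "same_host")] |>
                       dplyr::rename(context_all = "category"),
                     by = "family_id") |>
    dplyr::left_join(ctx_exp[, c("family_id", "category")] |>
                       dplyr::rename(context_expressed = "category"),
                     by = "family_id") |>
    dplyr::mutate(
      eligible = dplyr::coalesce(.data$eligible, FALSE),
      switch = dplyr::coalesce(.data$switch, FALSE),
      n_top_members = dplyr::coalesce(.data$n_top_members, 0L),
      identical_pair = .data$family_id %in% identical_fams$family_id
    )

  report <- stage("report", summarize_classes(
    sno_summary, family_summary, same_top = same_top, cors = cors))

  structure(
    list(sno_summary = sno_summary, family_summary = family_summary,
         report = report, switches = st,
         params = list(threshold = threshold, inclusive = inclusive,
                       ddof = ddof, cor_method = cor_method,
                       identity = identity, tissues = tissues)),
    class = "snofam_result"
  )
}

#' Per-class aggregate statistics
#'
#' Computes the headline per-class statistics with explicit denominators:
#' percent of snoRNAs in multi-member families (denominator: all snoRNAs of
#' the class), percent expressed (all snoRNAs; also restricted to
#' multi-member families), percent of multi-member families expressing at
#' least half their members (families with >= 2 members), switch counts and
#' same-host fraction (families with >= 2 expressed members), same-top-tissue
#' fraction (families with >= 2 expressed members), genomic-context category
#' counts, the between-class Mann-Whitney test on diagonal distances and the
#' per-class size-abundance correlation.
#'
#' @param sno_summary Per-snoRNA summary tibble.
#' @param family_summary Per-family summary tibble.
#' @param same_top Optional precomputed [same_tissue_top_fraction()] tibble.
#' @param cors Optional precomputed [correlate_size_abundance()] tibble.
#' @return Nested report list (JSON-ready), with a `classes` block per box
#'   type and the cross-class `diag_distance_test`.
#' @export
summarize_classes <- function(sno_summary, family_summary, same_top = NULL,
                              cors = NULL) {
  pct <- function(k, n) if (n > 0) round(100 * k / n, 1) else NA_real_
  col_or_na <- function(df, col, na = NA) {
    if (col %in% names(df)) df[[col]] else rep(na, nrow(df))
  }
  classes <- list()
  for (cls in intersect(c("CD", "HACA"), unique(sno_summary$box_type))) {
    sno <- sno_summary[sno_summary$box_type == cls, ]
    fams <- family_summary[family_summary$box_type == cls, ]
    multi <- fams[fams$n_members >= 2, ]
    multi_ids <- multi$family_id
    elig <- fams[fams$n_expressed >= 2, ]
    in_multi <- sno$family_id %in% multi_ids
    classes[[cls]] <- list(
      n_snornas = nrow(sno),
      n_families = nrow(fams),
      n_multi_member_families = nrow(multi),
      pct_snornas_in_multi_member = pct(sum(in_multi), nrow(sno)),
      pct_expressed = pct(sum(sno$expressed), nrow(sno)),
      pct_expressed_multi_only = pct(sum(sno$expressed & in_multi),
                                     sum(in_multi)),
      families_ge_half_expressed = list(
        k = sum(multi$n_expressed >= multi$n_members / 2),
        n = nrow(multi),
        pct = pct(sum(multi$n_expressed >= multi$n_members / 2),
                  nrow(multi)),
        denominator = "families with >= 2 members"),
      n_switch_families = sum(elig$switch),
      n_switch_eligible = nrow(elig),
      same_host = list(
        k = sum(elig$same_host, na.rm = TRUE), n = nrow(elig),
        pct = pct(sum(elig$same_host, na.rm = TRUE), nrow(elig)),
        denominator = "families with >= 2 expressed members"),
      context_all = as.list(table(col_or_na(fams, "context_all",
                                            NA_character_))),
      context_expressed = as.list(table(col_or_na(fams, "context_expressed",
                                                  NA_character_))),
      n_identical_pair_families =
        sum(col_or_na(fams, "identical_pair", NA), na.rm = TRUE),
      mean_pairwise_identity = {
        aln <- col_or_na(sno, "alignment_score", NA_real_)
        if (all(is.na(aln))) NA_real_ else
          round(mean(aln, na.rm = TRUE), 1)
      }
    )
    if (nrow(sno) == 0) {
      warning("empty class omitted from report: ", cls)
      classes[[cls]] <- NULL
    }
  }
  if (!is.null(same_top)) {
    for (i in seq_len(nrow(same_top))) {
      cls <- same_top$box_type[i]
      if (!is.null(classes[[cls]])) {
        classes[[cls]]$same_top_tissue <- list(
          k = same_top$k[i], n = same_top$n[i],
          fraction = same_top$fraction[i],
          denominator = "families with >= 2 expressed members")
      }
    }
  }
  if (!is.null(cors)) {
    for (i in seq_len(nrow(cors))) {
      cls <- cors$box_type[i]
      if (!is.null(classes[[cls]])) {
        classes[[cls]]$size_abundance_correlation <- list(
          r = cors$r[i], p_value = cors$p_value[i], n = cors$n[i],
          method = cors$method[i])
      }
    }
  }
  report <- list(classes = classes)
  dd <- col_or_na(family_summary, "diag_distance", NA_real_)
  dd_cd <- dd[family_summary$box_type == "CD"]
  dd_ha <- dd[family_summary$box_type == "HACA"]
  dd_cd <- dd_cd[!is.na(dd_cd)]
  dd_ha <- dd_ha[!is.na(dd_ha)]
  if (length(dd_cd) > 0 && length(dd_ha) > 0) {
    mwu <- compare_classes_diag(dd_cd, dd_ha)
    report$diag_distance_test <- list(U = mwu$statistic,
                                      p_value = mwu$p_value,
                                      n_cd = mwu$n_cd, n_haca = mwu$n_haca)
  }
  report
}

#' Write pipeline outputs to a directory
#'
#' Emits `sno_summary.tsv`, `family_summary.tsv`, `report.json` and the
#' categorical heatmap matrix `top_member_matrix.tsv`. Deterministic: the
#' same result writes byte-identical files.
#'
#' @param result A `snofam_result`.
#' @param dir Output directory (created if missing).
#' @return Named paths, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "snofam_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sno = file.path(dir, "sno_summary.tsv"),
             family = file.path(dir, "family_summary.tsv"),
             report = file.path(dir, "report.json"),
             heatmap = file.path(dir, "top_member_matrix.tsv"))
  readr::write_tsv(result$sno_summary, paths[["sno"]], progress = FALSE)
  fam <- result$family_summary
  readr::write_tsv(fam, paths[["family"]], progress = FALSE)
  jsonlite::write_json(result$report, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  readr::write_tsv(top_member_matrix(result$switches), paths[["heatmap"]],
                   progress = FALSE)
  invisible(paths)
}

#' @export
print.snofam_result <- function(x, ...) {
  cat(sprintf(
    "<snofam_result> %d snoRNAs, %d families; %d expressed snoRNAs; %d switch families\n",
    nrow(x$sno_summary), nrow(x$family_summary),
    sum(x$sno_summary$expressed), sum(x$family_summary$switch)))
  invisible(x)
}

#' @export
tidy.snofam_result <- function(x, ...) x$family_summary

#' @export
glance.snofam_result <- function(x, ...) {
  tibble::tibble(
    n_snornas = nrow(x$sno_summary),
    n_families = nrow(x$family_summary),
    n_expressed = sum(x$sno_summary$expressed),
    n_switch_families = sum(x$family_summary$switch),
    threshold = x$params$threshold
  )
}
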