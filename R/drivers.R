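# Rule-based driver screening against an established cancer-gene list.
# Rules, with their thresholds:
#   TSG_DELETERIOUS  - coding variant in a TSG annotated functionally
#                      deleterious (annotation is an input, not computed)
#   TSG_HOMDEL_FOCAL - total copy number 0 over a TSG, segment span < 1 Mb
#   TSG_DISRUPTED_SV - rearrangement break end inside a TSG body
#   ONC_HOTSPOT      - oncogene variant at a previously reported hotspot
#   ONC_AMP_FOCAL    - segment span < 1 Mb, total copy number >= 5 (diploid
#                      genomes), fully containing the intact oncogene

role_is_tsg <- function(role) role %in% c("TSG", "both")
role_is_onc <- function(role) role %in% c("oncogene", "both")

driver_call <- function(gene, rule, evidence) {
  data.frame(gene = gene, rule = rule, evidence = evidence,
             stringsAsFactors = FALSE)
}

empty_driver_calls <- function() {
  data.frame(gene = character(), rule = character(), evidence = character(),
             stringsAsFactors = FALSE)
}

#' Screen annotated small variants for driver events
#'
#' @param variants data.frame with columns `gene`, `deleterious` (logical),
#'   `hotspot` (logical), plus any identifying columns (e.g. from
#'   [read_annotated_vcf()]).
#' @param cancer_genes data.frame with columns `gene`, `role`.
#' @return data.frame of driver calls (`gene`, `rule`, `evidence`).
#' @export
screen_small_variants <- function(variants, cancer_genes) {
  calls <- empty_driver_calls()
  for (i in seq_len(nrow(variants))) {
    hit <- match(variants$gene[i], cancer_genes$gene)
    if (is.na(hit)) next
    role <- cancer_genes$role[hit]
    ev <- sprintf("%s:%s", variants$chrom[i] %||% "?",
                  variants$pos[i] %||% i)
    if (role_is_tsg(role) && isTRUE(variants$deleterious[i]))
      calls <- rbind(calls, driver_call(variants$gene[i],
                                        "TSG_DELETERIOUS", ev))
    if (role_is_onc(role) && isTRUE(variants$hotspot[i]))
      calls <- rbind(calls, driver_call(variants$gene[i],
                                        "ONC_HOTSPOT", ev))
  }
  calls
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen copy-number segments for driver events
#'
#' Homozygous deletions must be focal (span strictly under
#' `focal_max_span`, default 1 Mb) and touch a listed TSG. Amplifications
#' must be focal, reach `amp_min_total_cn` total copies (default 5,
#' diploid) and contain the listed oncogene in full ("amplified the intact
#' gene").
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `total_cn`, `minor_cn`.
#' @param genes Named list of [gene_model] (for gene bodies).
#' @param cancer_genes data.frame with columns `gene`, `role`.
#' @param params A [fusion_params] (uses `focal_max_span`,
#'   `amp_min_total_cn`).
#' @return data.frame of driver calls.
#' @export
screen_cnv <- function(segments, genes, cancer_genes,
                       params = fusion_params()) {
  calls <- empty_driver_calls()
  for (i in seq_len(nrow(segments))) {
    span <- segments$end[i] - segments$start[i]
    if (span >= params$focal_max_span) next
    seg <- genomic_interval(segments$chrom[i], segments$start[i],
                            segments$end[i])
    for (g in genes) {
      hit <- match(g$name, cancer_genes$gene)
      if (is.na(hit)) next
      role <- cancer_genes$role[hit]
      ev <- sprintf("%s:%d-%d cn=%d", seg$chrom, seg$start, seg$end,
                    segments$total_cn[i])
      if (role_is_tsg(role) && segments$total_cn[i] == 0L &&
          iv_overlaps(seg, g$body))
        calls <- rbind(calls, driver_call(g$name, "TSG_HOMDEL_FOCAL", ev))
      contained <- seg$chrom == g$body$chrom &&
        seg$start <= g$body$start && seg$end >= g$body$end
      if (role_is_onc(role) &&
          segments$total_cn[i] >= params$amp_min_total_cn && contained)
        calls <- rbind(calls, driver_call(g$name, "ONC_AMP_FOCAL", ev))
    }
  }
  calls
}

#' Screen rearrangement break ends for TSG disruption
#'
#' @param rearrs List of [rearrangement].
#' @param genes Named list of [gene_model].
#' @param cancer_genes data.frame with columns `gene`, `role`.
#' @return data.frame of driver calls.
#' @export
screen_sv <- function(rearrs, genes, cancer_genes) {
  calls <- empty_driver_calls()
  for (r in rearrs) {
    for (e in list(r$end1, r$end2)) {
      ctx <- annotate_breakend(e, genes)
      if (is.na(ctx$gene_id)) next
      g <- genes[[ctx$gene_id]]
      hit <- match(g$name, cancer_genes$gene)
      if (is.na(hit) || !role_is_tsg(cancer_genes$role[hit])) next
      calls <- rbind(calls, driver_call(
        g$name, "TSG_DISRUPTED_SV",
        sprintf("%s:%d (%s)", e$chrom, e$pos, r$sample_id)))
    }
  }
  calls
}
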