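# GFF3 reading/writing of single-transcript gene models via rtracklayer.
# GFF3 is 1-based closed; conversion happens here and nowhere else.

# Map a transcript-coordinate interval back to one genomic interval.
# Only intervals contained in a single exon are representable (the generator
# guarantees this for regulatory elements); spanning intervals error.
transcript_to_genomic <- function(gene, tstart, tend) {
  off <- 0L
  for (i in seq_len(nrow(gene$exons))) {
    s <- gene$exons$start[i]; e <- gene$exons$end[i]
    w <- e - s
    if (tstart >= off && tend <= off + w) {
      if (gene$body$strand == "-") {
        return(c(start = e - (tend - off), end = e - (tstart - off)))
      }
      return(c(start = s + (tstart - off), end = s + (tend - off)))
    }
    off <- off + w
  }
  stop("transcript interval spans an exon junction; not representable as one GFF feature")
}

# Per-exon genomic pieces of a transcript-coordinate interval (used for CDS).
transcript_to_genomic_pieces <- function(gene, tstart, tend) {
  out <- list(); off <- 0L
  for (i in seq_len(nrow(gene$exons))) {
    s <- gene$exons$start[i]; e <- gene$exons$end[i]
    w <- e - s
    lo <- max(tstart, off); hi <- min(tend, off + w)
    if (lo < hi) {
      if (gene$body$strand == "-") {
        out[[length(out) + 1L]] <- c(start = e - (hi - off), end = e - (lo - off))
      } else {
        out[[length(out) + 1L]] <- c(start = s + (lo - off), end = s + (hi - off))
      }
    }
    off <- off + w
  }
  out
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS features plus `regulatory_region` features for
#' annotated regulatory elements; the gene's cancer role is kept as a `role`
#' attribute so models round-trip.
#'
#' @param genes List of [gene_model].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  rows <- list()
  add <- function(chrom, start0, end0, strand, type, id, parent, name = NA,
                  label = NA, role = NA, phase = NA_integer_) {
    cc <- zero_to_one_based(start0, end0)
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = cc$start, end = cc$end, strand = strand,
      type = type, ID = id, Parent = parent, Name = name, label = label,
      role = role, phase = phase, stringsAsFactors = FALSE)
  }
  for (g in genes) {
    b <- g$body
    mrna_id <- paste0(g$gene_id, ".t1")
    add(b$chrom, b$start, b$end, b$strand, "gene", g$gene_id, NA,
        name = g$name, role = g$role)
    add(b$chrom, b$start, b$end, b$strand, "mRNA", mrna_id, g$gene_id)
    for (i in seq_len(nrow(g$exons))) {
      add(b$chrom, g$exons$start[i], g$exons$end[i], b$strand, "exon",
          paste0(mrna_id, ".exon", i), mrna_id)
    }
    if (!is.na(g$cds_start)) {
      pieces <- transcript_to_genomic_pieces(g, g$cds_start, g$cds_end)
      done <- 0L
      for (j in seq_along(pieces)) {
        add(b$chrom, pieces[[j]]["start"], pieces[[j]]["end"], b$strand, "CDS",
            paste0(mrna_id, ".cds", j), mrna_id,
            phase = (3L - done %% 3L) %% 3L)
        done <- done + (pieces[[j]]["end"] - pieces[[j]]["start"])
      }
    }
    if (nrow(g$regulatory_elements)) {
      re <- g$regulatory_elements
      for (k in seq_len(nrow(re))) {
        gc <- transcript_to_genomic(g, re$start[k], re$end[k])
        add(b$chrom, gc["start"], gc["end"], b$strand, "regulatory_region",
            paste0(mrna_id, ".re", k), mrna_id, label = re$label[k])
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$Name <- df$Name
  S4Vectors::mcols(gr)$label <- df$label
  S4Vectors::mcols(gr)$role <- df$role
  S4Vectors::mcols(gr)$phase <- as.integer(df$phase)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects a gene/mRNA/exon/CDS hierarchy with one mRNA per gene. GFF3
#' 1-based closed coordinates are converted to the internal 0-based
#' half-open convention; minus-strand exons come back ordered 5'->3' in
#' transcript order. CDS and `regulatory_region` features are mapped into
#' spliced-transcript coordinates.
#'
#' @param path GFF3 file.
#' @return Named list of [gene_model] (names = gene ids).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  ids <- as.character(mc$ID)
  parent <- vapply(seq_along(gr), function(i) {
    p <- mc$Parent[[i]]
    if (length(p) == 0L || is.na(p[1]) || p[1] == "") NA_character_
    else as.character(p[1])
  }, character(1))
  st0 <- one_to_zero_based(GenomicRanges::start(gr), GenomicRanges::end(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))

  gene_idx <- which(type == "gene")
  mrna_idx <- which(type == "mRNA")
  mrna_gene <- structure(parent[mrna_idx], names = ids[mrna_idx])
  known_mrna <- ids[mrna_idx]

  child_idx <- which(type %in% c("exon", "CDS", "regulatory_region"))
  bad <- child_idx[!(parent[child_idx] %in% known_mrna)]
  if (length(bad))
    stop(sprintf("GFF3 format error: feature %d (%s '%s') has no mRNA parent",
                 bad[1], type[bad[1]],
                 ifelse(is.na(ids[bad[1]]), "<no ID>", ids[bad[1]])))

  genes <- list()
  for (gi in gene_idx) {
    gid <- ids[gi]
    strand_g <- if (strand[gi] %in% c("+", "-")) strand[gi] else "*"
    body <- genomic_interval(chrom[gi], st0$start[gi], st0$end[gi], strand_g)
    mrna <- names(mrna_gene)[mrna_gene == gid]
    if (length(mrna) != 1L)
      stop(sprintf("gene %s must have exactly one mRNA (found %d)",
                   gid, length(mrna)))
    ex_i <- which(type == "exon" & parent == mrna)
    ex <- data.frame(start = st0$start[ex_i], end = st0$end[ex_i])
    ex <- ex[order(ex$start, decreasing = (strand_g == "-")), , drop = FALSE]
    rownames(ex) <- NULL
    role <- if (!is.null(mc$role) && !is.na(mc$role[gi]))
      as.character(mc$role[gi]) else "none"
    g <- gene_model(gid, name = ifelse(is.na(mc$Name[gi]), gid,
                                       as.character(mc$Name[gi])),
                    body = body, exons = ex, role = role)
    cds_i <- which(type == "CDS" & parent == mrna)
    if (length(cds_i)) {
      tc <- unlist(lapply(cds_i, function(i) {
        c(genomic_to_transcript(g, st0$start[i]),
          genomic_to_transcript(g, st0$end[i] - 1L))
      }))
      g$cds_start <- min(tc); g$cds_end <- max(tc) + 1L
    }
    re_i <- which(type == "regulatory_region" & parent == mrna)
    if (length(re_i)) {
      tc <- t(vapply(re_i, function(i) {
        a <- genomic_to_transcript(g, st0$start[i])
        b <- genomic_to_transcript(g, st0$end[i] - 1L)
        range(c(a, b))
      }, numeric(2)))
      g$regulatory_elements <- data.frame(
        label = as.character(mc$label[re_i]),
        start = as.integer(tc[, 1]), end = as.integer(tc[, 2]) + 1L,
        stringsAsFactors = FALSE)
    }
    genes[[gid]] <- g
  }
  genes
}

#' Assign cancer-gene roles from a gene-list table
#'
#' @param genes Named list of [gene_model].
#' @param cancer_genes data.frame with columns `gene` (symbol) and `role`,
#'   as read by [read_cancer_genes()].
#' @return The gene list with `role` fields updated.
#' @export
apply_cancer_roles <- function(genes, cancer_genes) {
  for (i in seq_along(genes)) {
    hit <- match(genes[[i]]$name, cancer_genes$gene)
    if (!is.na(hit)) genes[[i]]$role <- cancer_genes$role[hit]
  }
  genes
}
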