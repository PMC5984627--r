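#' Gene model
#'
#' A single-transcript gene model: the pipeline reasons at gene level, so one
#' transcript per gene is assumed throughout. Exons are stored as genomic
#' 0-based half-open intervals ordered 5'->3' in *transcript* order (i.e.
#' descending genomic coordinate for minus-strand genes). The CDS and any
#' regulatory elements are stored in spliced-transcript coordinates.
#'
#' @param gene_id Stable identifier.
#' @param name Gene symbol.
#' @param body [genomic_interval] spanning the gene.
#' @param exons data.frame with integer columns `start`, `end` (genomic,
#'   0-based half-open), rows in transcript order.
#' @param cds_start,cds_end CDS bounds in spliced-transcript coordinates
#'   (0-based half-open; `cds_end` includes the stop codon).
#' @param role Cancer-gene role: `"oncogene"`, `"TSG"`, `"both"` or `"none"`.
#' @param regulatory_elements data.frame with columns `label`, `start`, `end`
#'   (transcript coordinates), e.g. an mRNA instability determinant or an
#'   AU-rich element in the 3' UTR.
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(gene_id, name, body, exons,
                       cds_start = NA_integer_, cds_end = NA_integer_,
                       role = "none",
                       regulatory_elements = empty_regulatory()) {
  stopifnot(inherits(body, "genomic_interval"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            role %in% c("oncogene", "TSG", "both", "none"))
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  if (any(exons$start >= exons$end)) stop("exon with start >= end")
  if (any(exons$start < body$start) || any(exons$end > body$end))
    stop("exon outside gene body")
  gs <- sort(exons$start)
  ge <- sort(exons$end)
  if (nrow(exons) > 1L && any(gs[-1L] < ge[-nrow(exons)]))
    stop("overlapping exons")
  # transcript order: ascending genomic on +, descending on -
  ord <- order(exons$start, decreasing = (body$strand == "-"))
  if (!identical(ord, seq_len(nrow(exons))))
    stop("exons not in transcript order")
  tl <- sum(exons$end - exons$start)
  if (!is.na(cds_start)) {
    cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
    if (cds_start >= cds_end || cds_end > tl)
      stop("cds bounds outside spliced transcript")
  }
  re <- regulatory_elements
  if (nrow(re)) {
    if (any(re$start < 0L) || any(re$end > tl))
      stop("regulatory element outside spliced transcript")
  }
  structure(list(gene_id = gene_id, name = name, body = body, exons = exons,
                 cds_start = cds_start, cds_end = cds_end, role = role,
                 regulatory_elements = re),
            class = "gene_model")
}

empty_regulatory <- function() {
  data.frame(label = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Spliced transcript length of a gene model
#' @param gene A [gene_model].
#' @return Integer length in nt.
#' @export
transcript_length <- function(gene) sum(gene$exons$end - gene$exons$start)

#' Map a genomic position into spliced-transcript coordinates
#'
#' @param gene A [gene_model].
#' @param gpos 0-based genomic position; must fall inside an exon.
#' @return 0-based transcript coordinate, or `NA` if `gpos` is not exonic.
#' @export
genomic_to_transcript <- function(gene, gpos) {
  off <- 0L
  for (i in seq_len(nrow(gene$exons))) {
    s <- gene$exons$start[i]; e <- gene$exons$end[i]
    if (gpos >= s && gpos < e) {
      return(if (gene$body$strand == "-") off + (e - 1L - gpos)
             else off + (gpos - s))
    }
    off <- off + (e - s)
  }
  NA_integer_
}

#' Extract the spliced transcript sequence of a gene
#'
#' @param gene A [gene_model].
#' @param genome A named `Biostrings::DNAStringSet`.
#' @return Character scalar, transcript (sense-strand) sequence.
#' @export
spliced_sequence <- function(gene, genome) {
  chr <- genome[[gene$body$chrom]]
  parts <- vapply(seq_len(nrow(gene$exons)), function(i) {
    s <- gene$exons$start[i]; e <- gene$exons$end[i]
    seg <- Biostrings::subseq(chr, start = s + 1L, end = e)
    if (gene$body$strand == "-") seg <- Biostrings::reverseComplement(seg)
    as.character(seg)
  }, character(1))
  paste0(parts, collapse = "")
}

#' Fetch plus-strand genomic sequence for an interval
#' @param genome Named `DNAStringSet`.
#' @param iv A [genomic_interval].
#' @return Character scalar.
#' @export
genome_sequence <- function(genome, iv) {
  as.character(Biostrings::subseq(genome[[iv$chrom]],
                                  start = iv$start + 1L, end = iv$end))
}
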