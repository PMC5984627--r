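# BEDPE interchange for structural-variant calls. BEDPE is 0-based
# half-open; break ends are written as width-1 intervals whose start is the
# junction position. Column 11, when present, carries the non-template
# insert sequence ('.' or '' = none).

#' Read structural variants from BEDPE
#'
#' @param path BEDPE file with >= 10 columns
#'   (chrom1 start1 end1 chrom2 start2 end2 name score strand1 strand2
#'   \[insert\]). An empty file yields an empty list.
#' @param sample_id Sample label attached to each record.
#' @param evidence Evidence tier attached to each record.
#' @return List of [rearrangement].
#' @export
read_bedpe <- function(path, sample_id = "sample", evidence = "DNA") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(list())
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(df) < 10L) stop("BEDPE requires at least 10 columns")
  lapply(seq_len(nrow(df)), function(i) {
    ins <- if (ncol(df) >= 11L) as.character(df[i, 11L]) else ""
    if (is.na(ins) || ins == ".") ins <- ""
    rearrangement(
      break_end(df[i, 1L], df[i, 2L], strand_to_orientation(df[i, 9L])),
      break_end(df[i, 4L], df[i, 5L], strand_to_orientation(df[i, 10L])),
      non_template_insert = ins,
      sample_id = sample_id, evidence = evidence)
  })
}

#' Write structural variants to BEDPE
#'
#' @param rearrs List of [rearrangement].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(rearrs, path) {
  if (!length(rearrs)) { writeLines(character(), path); return(invisible(path)) }
  rows <- vapply(seq_along(rearrs), function(i) {
    r <- rearrs[[i]]
    paste(r$end1$chrom, r$end1$pos, r$end1$pos + 1L,
          r$end2$chrom, r$end2$pos, r$end2$pos + 1L,
          paste0(r$sample_id, "_sv", i), ".",
          orientation_to_strand(r$end1$orientation),
          orientation_to_strand(r$end2$orientation),
          ifelse(nchar(r$non_template_insert), r$non_template_insert, "."),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
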