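# File-format boundaries. Sequences travel as FASTA (via Biostrings),
# cross-links, peaks and binding sites as BED6, tables as TSV. Internally all
# coordinates are 1-based closed; BED I/O converts to 0-based half-open.

#' Write / read 3'UTR records as FASTA
#'
#' One record per gene; the description carries the regulation class and the
#' 1-based PAS start so records round-trip.
#'
#' @param records tibble with `gene`, `class`, `seq`, `pas_start`.
#' @param path FASTA file path.
#' @return `write_utr_fasta()` returns `path` invisibly; `read_utr_fasta()`
#'   returns a records tibble.
#' @export
write_utr_fasta <- function(records, path) {
  assert_columns(records, c("gene", "class", "seq", "pas_start"))
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- sprintf("%s class=%s pas_start=%d", records$gene, records$class,
                      records$pas_start)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' @rdname write_utr_fasta
#' @export
read_utr_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  parse_field <- function(field) {
    sub(sprintf(".*%s=(\\S+).*", field), "\\1", hdr)
  }
  tibble(
    gene = sub(" .*", "", hdr),
    class = parse_field("class"),
    width = Biostrings::width(x),
    seq = as.character(x),
    pas_start = as.integer(parse_field("pas_start"))
  )
}

#' Write / read a cross-link track as BED6
#'
#' `chrom` is the gene id (transcript coordinate space), `start`/`end` are the
#' 0-based half-open single-nucleotide interval of the cross-link, `name` the
#' sample, `score` the cDNA count and `strand` the strand (the simulator emits
#' `+` only; readers preserve whatever strand is present).
#'
#' @param track tibble with `sample`, `gene`, `pos`, `count` (and optionally
#'   `strand`).
#' @param path BED file path.
#' @param seed optional seed recorded as a `# seed:` header comment.
#' @return `write_crosslink_bed()` returns `path` invisibly;
#'   `read_crosslink_bed()` returns a track tibble (1-based `pos`).
#' @export
write_crosslink_bed <- function(track, path, seed = NULL) {
  assert_columns(track, c("sample", "gene", "pos", "count"))
  strand <- track[["strand"]] %||% rep("+", nrow(track))
  bed <- tibble(
    chrom = track$gene, start = track$pos - 1L, end = track$pos,
    name = track$sample, score = track$count, strand = strand
  )
  header <- if (!is.null(seed)) sprintf("# seed: %d", seed) else character(0)
  writeLines(c(header, sprintf("%s\t%d\t%d\t%s\t%d\t%s", bed$chrom, bed$start,
                               bed$end, bed$name, bed$score, bed$strand)), path)
  invisible(path)
}

#' @rdname write_crosslink_bed
#' @export
read_crosslink_bed <- function(path) {
  bed <- readr::read_tsv(
    path, comment = "#", progress = FALSE, show_col_types = FALSE,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic"
  )
  tibble(
    sample = bed$name, gene = bed$chrom, pos = bed$start + 1L,
    count = bed$score, strand = bed$strand
  )
}

#' Write a tibble as TSV with a seed header comment
#'
#' @param x a data frame.
#' @param path file path.
#' @param seed optional integer recorded as `# seed:`.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path, seed = NULL) {
  header <- if (!is.null(seed)) sprintf("# seed: %d", seed) else character(0)
  writeLines(header, path)
  suppressMessages(readr::write_tsv(x, path, append = length(header) > 0,
                                    col_names = TRUE))
  invisible(path)
}

#' Read a TSV written by [write_table_tsv()]
#' @param path file path.
#' @return a tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", progress = FALSE, show_col_types = FALSE)
}
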