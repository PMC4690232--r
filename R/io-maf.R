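# MAF (LAST dialect) reader/writer.
#
# Each "a" paragraph must contain exactly two "s" lines: the reference row
# first, the query scaffold second. Internal coordinates are 0-based
# half-open on the forward strand of each sequence; minus-strand query
# coordinates are converted at parse time and the strand kept as a flag.
# The gapped alignment texts are retained verbatim (for a minus-strand
# query the text is the reverse-complemented query, as in the file).

#' Read a pairwise MAF file into an alignment-block tibble
#'
#' @param path path to a MAF file (two `s` lines per `a` paragraph,
#'   reference row first).
#' @return tibble with one row per alignment block: `ref_chrom`, `ref_start`,
#'   `ref_end`, `ref_srcsize`, `q_name`, `q_start`, `q_end`, `q_srcsize`,
#'   `strand`, `score`, `ref_text`, `q_text`. Coordinates are 0-based
#'   half-open on the forward strand.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  a_idx <- grep("^a\\b", lines)
  if (length(a_idx) == 0L) return(empty_block_tbl())
  bounds <- c(a_idx, length(lines) + 1L)
  blocks <- vector("list", length(a_idx))
  for (b in seq_along(a_idx)) {
    par <- lines[a_idx[b]:(bounds[b + 1L] - 1L)]
    s_lines <- par[grepl("^s\\s", par)]
    if (length(s_lines) != 2L) {
      abort(paste0("MAF paragraph ", b, " has ", length(s_lines),
                   " sequence lines (expected 2)"))
    }
    score <- suppressWarnings(as.numeric(sub("^a\\s+score=([-0-9.eE+]+).*$", "\\1", par[1])))
    if (is.na(score)) score <- 0
    r <- parse_s_line(s_lines[1])
    q <- parse_s_line(s_lines[2])
    if (r$strand != "+") abort("reference row of a MAF block must be + strand")
    blocks[[b]] <- tibble(
      ref_chrom = r$name, ref_start = r$fwd_start, ref_end = r$fwd_end,
      ref_srcsize = r$srcsize,
      q_name = q$name, q_start = q$fwd_start, q_end = q$fwd_end,
      q_srcsize = q$srcsize, strand = q$strand, score = score,
      ref_text = r$text, q_text = q$text
    )
  }
  dplyr::bind_rows(blocks)
}

parse_s_line <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(f) != 7L) abort(paste0("malformed MAF s line: ", line))
  start <- as.numeric(f[3]); size <- as.numeric(f[4]); src <- as.numeric(f[6])
  if (is.na(start) || is.na(size) || is.na(src) || size <= 0) {
    abort(paste0("malformed MAF s line: ", line))
  }
  strand <- f[5]
  if (!strand %in% c("+", "-")) abort(paste0("bad strand in MAF s line: ", line))
  fwd_start <- if (strand == "+") start else src - start - size
  txt <- gsub("[^ACGTN-]", "N", toupper(f[7]))   # keep gap columns
  list(name = f[2], fwd_start = fwd_start, fwd_end = fwd_start + size,
       srcsize = src, strand = strand, text = txt)
}

empty_block_tbl <- function() {
  tibble(
    ref_chrom = character(), ref_start = numeric(), ref_end = numeric(),
    ref_srcsize = numeric(), q_name = character(), q_start = numeric(),
    q_end = numeric(), q_srcsize = numeric(), strand = character(),
    score = numeric(), ref_text = character(), q_text = character()
  )
}

#' Write an alignment-block tibble as MAF
#'
#' Inverse of [read_maf()]: forward-strand query coordinates are converted
#' back to strand-relative MAF starts on output.
#'
#' @param blocks block tibble as returned by [read_maf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    writeLines(sprintf("a score=%g", b$score), con)
    writeLines(sprintf("s %s %d %d + %d %s", b$ref_chrom,
                       as.integer(b$ref_start),
                       as.integer(b$ref_end - b$ref_start),
                       as.integer(b$ref_srcsize), b$ref_text), con)
    q_size <- as.integer(b$q_end - b$q_start)
    q_start_maf <- if (b$strand == "+") b$q_start else b$q_srcsize - b$q_end
    writeLines(sprintf("s %s %d %d %s %d %s", b$q_name,
                       as.integer(q_start_maf), q_size, b$strand,
                       as.integer(b$q_srcsize), b$q_text), con)
    writeLines("", con)
  }
  invisible(path)
}
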