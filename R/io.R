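# Annotation and alignment-chain I/O. Readers accept gzip transparently
# (handled by rtracklayer / base connections). GTF is 1-based closed on disk
# and in memory; BED and chain are 0-based half-open on disk and converted
# to 1-based closed GRanges / block tables on read.

#' Read a GTF file
#'
#' Thin wrapper over [rtracklayer::import()] returning a `GRanges` with the
#' usual attribute columns (`type`, `gene_id`, `transcript_id`,
#' `gene_biotype` when present).
#'
#' @param path Path to a GTF file (optionally gzipped).
#' @return `GRanges` of records.
#' @export
read_gtf <- function(path) {
  rtracklayer::import(path, format = "gtf")
}

#' Write exon records to a GTF file
#'
#' Deterministic writer: identical input produces byte-identical files (no
#' timestamp headers). Expects metadata columns `transcript_id`, `gene_id`
#' and optionally `gene_biotype` and `type` (default `"exon"`).
#'
#' @param x `GRanges` with `transcript_id`/`gene_id` metadata columns.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path, source = "lncage") {
  stopifnot(is(x, "GRanges"),
            all(c("transcript_id", "gene_id") %in% names(mcols(x))))
  type <- if ("type" %in% names(mcols(x))) as.character(mcols(x)$type) else "exon"
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   mcols(x)$gene_id, mcols(x)$transcript_id)
  if ("gene_biotype" %in% names(mcols(x))) {
    attrs <- paste(attrs, sprintf('gene_biotype "%s";', mcols(x)$gene_biotype))
  }
  lines <- paste(as.character(seqnames(x)), source, type,
                 start(x), end(x), ".", as.character(strand(x)), ".",
                 attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file
#'
#' Wrapper over [rtracklayer::import()] with coordinate validation: rows
#' whose half-open interval is empty or inverted raise an error naming the
#' offending line.
#'
#' @param path Path to a BED file (optionally gzipped).
#' @return `GRanges`; BED `name`, `score`, `strand` become metadata/strand.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  bad <- which(width(gr) < 1L)
  if (length(bad)) {
    stop("BED record with start >= end at line ", bad[1L], " of ", path)
  }
  gr
}

#' Write intervals to a BED6 file
#'
#' Converts 1-based closed `GRanges` to 0-based half-open BED. The `name`
#' metadata column (TE family or TF name) is written when present.
#'
#' @param x `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(is(x, "GRanges"))
  nm <- if ("name" %in% names(mcols(x))) as.character(mcols(x)$name) else "."
  sc <- if ("score" %in% names(mcols(x))) mcols(x)$score else 0L
  lines <- paste(as.character(seqnames(x)), start(x) - 1L, end(x),
                 nm, sc, as.character(strand(x)), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# ---- UCSC chain format ----------------------------------------------------
#
# A chain is stored as a list with fields:
#   chain_id, score,
#   source_chrom/source_size/source_strand/source_start/source_end
#     (the genome coordinates the lift maps FROM; the `t` fields of the
#      on-disk header, as in UCSC over.chain files),
#   target_* (the genome mapped TO; the `q` fields),
#   blocks: data.frame(size, dsource, dtarget) where dsource/dtarget are the
#     unaligned gaps after each block on the source/target side; the last
#     block has both gaps 0.
# source_start/source_end and target_start/target_end are kept 0-based
# half-open exactly as on disk; block arithmetic uses them directly.

.validate_chain <- function(ch, where = "chain") {
  b <- ch$blocks
  if (nrow(b) < 1L) stop(where, ": chain has no blocks")
  if (b$dsource[nrow(b)] != 0L || b$dtarget[nrow(b)] != 0L) {
    stop(where, ": last block of chain ", ch$chain_id, " has nonzero gaps")
  }
  if (sum(b$size + b$dsource) != ch$source_end - ch$source_start) {
    stop(where, ": source span mismatch in chain ", ch$chain_id)
  }
  if (sum(b$size + b$dtarget) != ch$target_end - ch$target_start) {
    stop(where, ": target span mismatch in chain ", ch$chain_id)
  }
  invisible(TRUE)
}

#' Read a UCSC chain file
#'
#' Parses the standard chain syntax (`chain score tName tSize tStrand
#' tStart tEnd qName qSize qStrand qStart qEnd id` headers followed by
#' `size dt dq` block lines). The header `t` side becomes the lift *source*
#' and the `q` side the lift *target*, matching how UCSC over.chain files
#' are consumed by liftOver. Block-structure invariants are checked and a
#' violation raises a parse error naming the line.
#'
#' @param path Path to a chain file (optionally gzipped).
#' @return List of chain records (see package internals for fields).
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) { i <- i + 1L; next }
    f <- strsplit(line, "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) != 13L) {
      stop("malformed chain header at line ", i, " of ", path)
    }
    ch <- list(
      chain_id = f[13], score = as.numeric(f[2]),
      source_chrom = f[3], source_size = as.integer(f[4]),
      source_strand = f[5], source_start = as.integer(f[6]),
      source_end = as.integer(f[7]),
      target_chrom = f[8], target_size = as.integer(f[9]),
      target_strand = f[10], target_start = as.integer(f[11]),
      target_end = as.integer(f[12]))
    if (ch$source_strand != "+") {
      stop("chain with '-' source strand not supported, line ", i, " of ", path)
    }
    sizes <- integer(0); ds <- integer(0); dt <- integer(0)
    i <- i + 1L
    repeat {
      if (i > n) stop("truncated chain block section at line ", i, " of ", path)
      bl <- trimws(lines[i])
      if (bl == "") break
      bf <- suppressWarnings(as.integer(strsplit(bl, "[ \t]+")[[1]]))
      if (anyNA(bf) || !length(bf) %in% c(1L, 3L)) {
        stop("malformed chain block at line ", i, " of ", path)
      }
      sizes <- c(sizes, bf[1])
      if (length(bf) == 3L) { ds <- c(ds, bf[2]); dt <- c(dt, bf[3]); i <- i + 1L }
      else { ds <- c(ds, 0L); dt <- c(dt, 0L); i <- i + 1L; break }
    }
    ch$blocks <- data.frame(size = sizes, dsource = ds, dtarget = dt)
    .validate_chain(ch, where = paste0(path, " near line ", i))
    chains[[length(chains) + 1L]] <- ch
    i <- i + 1L
  }
  chains
}

#' Write chains to a UCSC chain file
#'
#' Inverse of [read_chain()]; `write_chain` then `read_chain` restores the
#' identical block structure.
#'
#' @param chains List of chain records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in chains) {
    .validate_chain(ch)
    writeLines(paste("chain", format(ch$score, scientific = FALSE),
                     ch$source_chrom, ch$source_size, ch$source_strand,
                     ch$source_start, ch$source_end,
                     ch$target_chrom, ch$target_size, ch$target_strand,
                     ch$target_start, ch$target_end, ch$chain_id), con)
    b <- ch$blocks
    if (nrow(b) > 1L) {
      writeLines(paste(b$size[-nrow(b)], b$dsource[-nrow(b)],
                       b$dtarget[-nrow(b)]), con)
    }
    writeLines(c(as.character(b$size[nrow(b)]), ""), con)
  }
  invisible(path)
}
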