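## File formats: FASTA/FASTQ input, TSV tracks and tables, JSON verdicts.
## All tabular outputs are TSV with '#' header comment lines; coordinates
## are 1-based inclusive.

#' Read sequences from FASTA or FASTQ
#'
#' The format is auto-detected from the first record character ('>' for
#' FASTA, '@' for FASTQ); gzipped files are handled transparently.  Bases
#' are uppercased; order and ids are preserved.
#'
#' @param path path to a FASTA or FASTQ file, optionally gzipped.
#' @return a named [Biostrings::DNAStringSet].
#' @export
readSequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rt")
  first <- tryCatch(readLines(con, n = 1L), finally = close(con))
  if (!length(first) || !nzchar(first))
    stop("empty sequence file: ", path)
  fmt <- if (startsWith(first, ">")) "fasta"
         else if (startsWith(first, "@")) "fastq"
         else stop("cannot detect the format of ", path,
                   " (expected FASTA or FASTQ)")
  if (fmt == "fastq") {
    con <- gzfile(path, "rt")
    lns <- tryCatch(readLines(con), finally = close(con))
    lns <- lns[seq_len(max(which(nzchar(lns)), 0L))]
    if (length(lns) %% 4L != 0L) {
      recId <- lns[4L * (length(lns) %/% 4L) + 1L]
      stop("truncated FASTQ record '", sub("^@", "", recId), "' in ", path)
    }
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) stop("malformed ", fmt, " in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!length(x)) stop("no records in ", path)
  nm <- names(x)
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- nm
  x
}

#' Write / read a position count track as TSV
#'
#' Header comment lines carry `total_reads`, `k` and the vector id;
#' columns are `position` and `count`.
#'
#' @param track a [PositionCountTrack-class].
#' @param path output path.
#' @return `writeTrack` invisibly returns `path`; `readTrack` returns the
#'   [PositionCountTrack-class].
#' @export
writeTrack <- function(track, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("# vector=", track@vectorId),
    paste0("# k=", track@k),
    paste0("# total_reads=", track@totalReads),
    "position\tcount"), con)
  write.table(data.frame(position = seq_along(track@counts),
                         count = track@counts),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeTrack
#' @export
readTrack <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  getval <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(ln)) stop("track header lacks '", key, "': ", path)
    sub(paste0("^# ", key, "="), "", ln[1L])
  }
  df <- read.table(path, sep = "\t", comment.char = "#", header = TRUE)
  counts <- integer(max(df$position))
  counts[df$position] <- df$count
  PositionCountTrack(counts, as.integer(getval("total_reads")),
                     as.integer(getval("k")), getval("vector"))
}

#' Write / read a significance track as TSV
#'
#' @param sig a [SignificanceTrack-class].
#' @param path output path.
#' @export
writeSignificance <- function(sig, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("# vector=", sig@vectorId),
    paste0("# k=", sig@k),
    paste0("# sample_total=", sig@sampleTotal),
    paste0("# control_total=", sig@controlTotal),
    paste0("# g_critical=", format(sig@gCritical, digits = 15))), con)
  df <- sig@stats
  df$G <- format(df$G, digits = 15)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' @rdname writeSignificance
#' @export
readSignificance <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  getval <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(ln)) stop("header lacks '", key, "': ", path)
    sub(paste0("^# ", key, "="), "", ln[1L])
  }
  df <- read.table(path, sep = "\t", comment.char = "#", header = TRUE,
                   stringsAsFactors = FALSE)
  df$G <- as.numeric(df$G)
  new("SignificanceTrack", stats = df,
      sampleTotal = as.integer(getval("sample_total")),
      controlTotal = as.integer(getval("control_total")),
      gCritical = as.numeric(getval("g_critical")),
      k = as.integer(getval("k")), vectorId = getval("vector"))
}

#' Write classified peaks as TSV
#'
#' @param peakSet an [IRanges::IRanges] with peak metadata columns.
#' @param path output path.
#' @export
writePeaks <- function(peakSet, path) {
  m <- S4Vectors::mcols(peakSet)
  df <- data.frame(start = IRanges::start(peakSet),
                   end = IRanges::end(peakSet),
                   maxG = if (length(peakSet)) m$maxG else numeric(0),
                   direction = if (length(peakSet)) m$direction else character(0),
                   meanSample = if (length(peakSet)) m$meanSample else numeric(0),
                   meanControl = if (length(peakSet)) m$meanControl else numeric(0),
                   stringsAsFactors = FALSE)
  if (!is.null(m$class)) df$class <- m$class
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a verdict as JSON
#'
#' @param verdict a [Verdict-class].
#' @param path output path.
#' @export
writeVerdict <- function(verdict, path) {
  m <- S4Vectors::mcols(verdict@peaks)
  pk <- lapply(seq_along(verdict@peaks), function(i) list(
    start = IRanges::start(verdict@peaks)[i],
    end = IRanges::end(verdict@peaks)[i],
    maxG = m$maxG[i], direction = m$direction[i],
    class = m$class[i], rationale = m$rationale[i]))
  obj <- list(
    foreign_free = verdict@foreignFree,
    peaks = pk,
    class_counts = as.list(verdict@classCounts),
    shared_regions = lapply(seq_along(verdict@sharedRegions), function(i)
      list(start = IRanges::start(verdict@sharedRegions)[i],
           end = IRanges::end(verdict@sharedRegions)[i])),
    config = list(k = verdict@config@k, g_critical = verdict@config@gCritical,
                  alpha = verdict@config@alpha,
                  peak_gap = verdict@config@peakGap,
                  multiple_testing = verdict@config@multipleTesting,
                  williams = verdict@config@williams))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeVerdict
#' @export
readVerdict <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Write / read an SNV table as TSV
#'
#' Columns: `contig`, `pos` (1-based), `ref`, `alt`.
#'
#' @param snvs data.frame of SNVs.
#' @param path file path.
#' @export
writeSnvTable <- function(snvs, path) {
  write.table(snvs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSnvTable
#' @export
readSnvTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             comment.char = "#")
}

#' Write vector features as TSV
#'
#' Columns: `name`, `start`, `end`, `strand` (always `+`; features are
#' given on the vector plus strand).
#'
#' @param vector a [VectorModel-class].
#' @param path file path.
#' @export
writeVectorFeatures <- function(vector, path) {
  fr <- featureRanges(vector)
  df <- data.frame(name = names(fr), start = IRanges::start(fr),
                   end = IRanges::end(fr), strand = "+",
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVectorFeatures
#' @export
readVectorFeatures <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             comment.char = "#")
}

#' Read a primer table
#'
#' TSV with columns `name`, `forward`, `reverse`, and optionally
#' `max_product`.
#'
#' @param path file path.
#' @return named list of [PrimerPair-class] objects.
#' @export
readPrimerPairs <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  stopifnot(all(c("name", "forward", "reverse") %in% names(df)))
  maxp <- if ("max_product" %in% names(df)) df$max_product else
    rep(5000L, nrow(df))
  out <- lapply(seq_len(nrow(df)), function(i)
    PrimerPair(df$forward[i], df$reverse[i], maxp[i]))
  names(out) <- df$name
  out
}

#' Write a genome or vector as FASTA
#'
#' @param x a [StrainGenome-class], [VectorModel-class] or
#'   [Biostrings::DNAStringSet].
#' @param path file path.
#' @param id sequence id used for a [VectorModel-class].
#' @export
writeFasta <- function(x, path, id = "vector") {
  if (is(x, "StrainGenome")) {
    seqs <- x@sequences
  } else if (is(x, "VectorModel")) {
    seqs <- Biostrings::DNAStringSet(as.character(vectorSequence(x)))
    names(seqs) <- id
  } else {
    seqs <- x
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
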