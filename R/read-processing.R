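# Raw junction FASTQ -> per-sample insertion profiles: inline-barcode
# demultiplexing, transposon-tag trimming, short-read filtering, unique
# seed-and-verify mapping, per-site tallying, and a funnel report.

#' Validate an inline barcode table
#'
#' Barcodes must be prefix-free (no barcode a prefix of another), otherwise
#' demultiplexing would be ambiguous for some reads.
#'
#' @param barcodes named character vector, `sample_id -> barcode`.
#' @return Invisibly `barcodes`; errors with class `tn_config_error` on a
#'   prefix violation, duplicate sample, or empty barcode.
#' @export
check_barcodes <- function(barcodes) {
  .assert(length(barcodes) > 0 && !is.null(names(barcodes)) &&
            all(nzchar(names(barcodes))), "barcodes must be named",
          "tn_config_error")
  .assert(!anyDuplicated(names(barcodes)), "duplicate sample ids",
          "tn_config_error")
  .assert(all(nzchar(barcodes)), "empty barcode", "tn_config_error")
  for (i in seq_along(barcodes)) for (j in seq_along(barcodes)) {
    if (i != j && startsWith(barcodes[[j]], barcodes[[i]]))
      .assert(FALSE, sprintf("barcode '%s' is a prefix of '%s'",
                             barcodes[[i]], barcodes[[j]]), "tn_config_error")
  }
  invisible(barcodes)
}

#' Demultiplex reads on exact inline barcode prefixes
#'
#' @param sequences character vector of read sequences.
#' @param barcodes prefix-free named barcode table (validated via
#'   [check_barcodes()]).
#' @return Character vector of sample ids, `NA` for reads matching no
#'   barcode.
#' @export
demultiplex <- function(sequences, barcodes) {
  check_barcodes(barcodes)
  out <- rep(NA_character_, length(sequences))
  for (s in names(barcodes)) {
    hit <- is.na(out) & startsWith(sequences, barcodes[[s]])
    out[hit] <- s
  }
  out
}

#' Locate and trim the transposon tag
#'
#' The leading `nchar(tag_seq)` bases (after barcode removal) must match the
#' transposon-end tag with at most `max_mismatch` substitutions; the
#' remainder is the genomic junction. Junctions shorter than
#' `min_junction_len` get the distinct status `"short"`.
#'
#' @param sequences read sequences with the barcode already removed.
#' @param tag_seq non-empty transposon tag.
#' @param max_mismatch allowed substitutions in the tag.
#' @param min_junction_len minimal junction length kept (default 20 bp).
#' @return list with `junction` (character, `NA` where rejected) and
#'   `status` (`"ok"`, `"tag_mismatch"`, `"short"`).
#' @export
trim_tag <- function(sequences, tag_seq, max_mismatch = 0,
                     min_junction_len = 20) {
  nt <- nchar(tag_seq)
  .assert(nt > 0, "tag_seq must be non-empty")
  n <- length(sequences)
  if (!n) return(list(junction = character(), status = character()))
  mm <- rep(0L, n)
  too_short <- nchar(sequences) < nt
  for (i in seq_len(nt)) {
    mm <- mm + (substr(sequences, i, i) != substr(tag_seq, i, i))
  }
  status <- rep("ok", n)
  status[mm > max_mismatch | too_short] <- "tag_mismatch"
  junction <- substring(sequences, nt + 1L)
  status[status == "ok" & nchar(junction) < min_junction_len] <- "short"
  junction[status != "ok"] <- NA_character_
  list(junction = junction, status = status)
}

#' Build a seed k-mer index of both genome strands
#'
#' @param genome a [tn_genome()].
#' @param seed_k seed length (default 20 bp, long enough for essentially
#'   unique placement in multi-Mb bacterial genomes).
#' @return An opaque index object consumed by [map_junctions()].
#' @export
build_genome_index <- function(genome, seed_k = 20) {
  L <- nchar(genome$sequence)
  .assert(L >= seed_k, "genome shorter than seed_k")
  fwd <- genome$sequence
  rc <- .revcomp(fwd)
  starts <- seq_len(L - seed_k + 1L)
  tab <- data.table::data.table(
    kmer = c(substring(fwd, starts, starts + seed_k - 1L),
             substring(rc, starts, starts + seed_k - 1L)),
    str = rep(c("F", "R"), each = length(starts)),
    pos = rep(starts, 2L))
  data.table::setkey(tab, kmer)
  list(fwd = fwd, rc = rc, L = L, seed_k = seed_k, table = tab,
       replicon_id = genome$replicon_id)
}

# mismatch count between equal-length strings (vectorised over pairs)
.hamming <- function(a, b) {
  out <- integer(length(a))
  diff <- a != b
  for (i in which(diff)) out[i] <- sum(charToRaw(a[i]) != charToRaw(b[i]))
  out
}

#' Map junction reads by exact seed match and mismatch-bounded verification
#'
#' A seed of `seed_k` bases is looked up exactly in the two-strand k-mer
#' index at up to three non-overlapping offsets (rescues reads whose first
#' seed carries a sequencing error); each candidate placement is then
#' verified over the full junction length, allowing at most `max_mismatch`
#' substitutions and no gaps. Placements are ranked by mismatch count: a
#' unique best placement maps the read, several tie as `"ambiguous"`
#' (discarded rather than randomly assigned), none leaves it `"unmapped"`.
#' The reported position is the first genomic base of the junction on the
#' matched strand; for a minus-strand junction this is its rightmost genomic
#' coordinate.
#'
#' @param junctions character vector of junction sequences.
#' @param index index from [build_genome_index()].
#' @param max_mismatch allowed substitutions in the verified junction.
#' @return data.frame with `position`, `strand`, `status`
#'   (`"mapped"`, `"ambiguous"`, `"unmapped"`); positions are `NA` unless
#'   mapped.
#' @export
map_junctions <- function(junctions, index, max_mismatch = 0) {
  k <- index$seed_k
  n <- length(junctions)
  res <- data.frame(position = rep(NA_integer_, n),
                    strand = rep(NA_character_, n),
                    status = rep("unmapped", n), stringsAsFactors = FALSE)
  if (!n) return(res)
  jl <- nchar(junctions)
  short <- jl < k
  todo <- which(!short)
  if (!length(todo)) return(res)

  uj <- unique(junctions[todo])
  ujl <- nchar(uj)
  cand <- vector("list", 3L)
  for (oi in 0:2) {
    off <- oi * k
    ok <- which(ujl >= off + k)
    if (!length(ok)) next
    seeds <- data.table::data.table(
      j = ok, off = off,
      kmer = substring(uj[ok], off + 1L, off + k))
    cand[[oi + 1L]] <- index$table[seeds, on = "kmer", nomatch = NULL]
  }
  hits <- data.table::rbindlist(cand)
  best_pos <- rep(NA_integer_, length(uj))
  best_str <- rep(NA_character_, length(uj))
  stat <- rep("unmapped", length(uj))
  if (nrow(hits)) {
    hits[, start := pos - off]
    hits <- hits[start >= 1L & start + ujl[j] - 1L <= index$L]
    hits <- unique(hits, by = c("j", "str", "start"))
    if (nrow(hits)) {
      target <- ifelse(hits$str == "F",
                       substring(index$fwd, hits$start, hits$start + ujl[hits$j] - 1L),
                       substring(index$rc, hits$start, hits$start + ujl[hits$j] - 1L))
      hits[, mm := .hamming(uj[j], target)]
      hits <- hits[mm <= max_mismatch]
      if (nrow(hits)) {
        hits[, best := mm == min(mm), by = j]
        hits <- hits[best == TRUE]
        nb <- hits[, .N, by = j]
        uniq <- nb$j[nb$N == 1L]
        multi <- nb$j[nb$N > 1L]
        stat[multi] <- "ambiguous"
        if (length(uniq)) {
          hu <- hits[j %in% uniq]
          gpos <- ifelse(hu$str == "F", hu$start, index$L - hu$start + 1L)
          best_pos[hu$j] <- as.integer(gpos)
          best_str[hu$j] <- ifelse(hu$str == "F", "+", "-")
          stat[hu$j] <- "mapped"
        }
      }
    }
  }
  m <- match(junctions[todo], uj)
  res$position[todo] <- best_pos[m]
  res$strand[todo] <- best_str[m]
  res$status[todo] <- stat[m]
  res
}

#' Tally mapped sites into an insertion profile
#'
#' @param sites data.frame with `position` and `strand` columns, one row per
#'   mapped read (all from one replicon).
#' @param sample_id sample name.
#' @param replicon_id replicon name.
#' @param collapse_strands if `TRUE`, merge the two strands of each position
#'   into a single "+" site.
#' @return A [tn_profile()]; `total_reads` equals `nrow(sites)`.
#' @export
tally_profile <- function(sites, sample_id, replicon_id = "chr",
                          collapse_strands = FALSE) {
  if (!nrow(sites)) {
    return(tn_profile(integer(), character(), integer(),
                      sample_id = sample_id, replicon_id = replicon_id))
  }
  str <- if (collapse_strands) rep("+", nrow(sites)) else sites$strand
  dt <- data.table::data.table(position = sites$position, strand = str)
  agg <- dt[, .(count = .N), by = .(position, strand)]
  tn_profile(agg$position, agg$strand, agg$count,
             sample_id = sample_id, replicon_id = replicon_id)
}

#' Process junction FASTQ reads into per-sample insertion profiles
#'
#' Runs the full funnel: exact barcode demultiplexing, tag trimming with a
#' mismatch budget, short-junction removal, seed-and-verify mapping (same
#' mismatch budget), and per-site tallying. Counter semantics: of
#' `total_reads`, `barcode_matched` carried a known barcode, `tag_matched`
#' additionally matched the tag, `passed_length_filter` also met
#' `min_junction_len`, and those split exactly into `mapped_unique`,
#' `mapped_ambiguous` and `unmapped`.
#'
#' @param reads data.frame from [read_fastq()]/[emit_reads()], or a FASTQ
#'   path (character).
#' @param genome a [tn_genome()] or a prebuilt [build_genome_index()].
#' @param barcodes named barcode table.
#' @param tag_seq transposon tag.
#' @param max_mismatch substitution budget for tag matching and mapping
#'   verification (default 2).
#' @param min_junction_len minimal junction length (default 20 bp).
#' @param seed_k mapping seed length (default `min_junction_len`).
#' @param collapse_strands collapse per-strand sites into positions.
#' @return list with `profiles` (named list of [tn_profile()], one per
#'   sample in `barcodes`), `report` (funnel counters), and `assignments`
#'   (per-read sample, position, strand, status).
#' @export
process_reads <- function(reads, genome, barcodes, tag_seq,
                          max_mismatch = 2, min_junction_len = 20,
                          seed_k = min_junction_len,
                          collapse_strands = FALSE) {
  if (is.character(reads)) reads <- read_fastq(reads)
  index <- if (is.list(genome) && !is.null(genome$seed_k)) genome else
    build_genome_index(genome, seed_k = seed_k)
  check_barcodes(barcodes)

  n <- nrow(reads)
  sample <- demultiplex(reads$sequence, barcodes)
  has_bc <- !is.na(sample)
  after_bc <- rep(NA_character_, n)
  after_bc[has_bc] <- substring(reads$sequence[has_bc],
                                nchar(barcodes[sample[has_bc]]) + 1L)

  status <- rep("no_barcode", n)
  junction <- rep(NA_character_, n)
  if (any(has_bc)) {
    tt <- trim_tag(after_bc[has_bc], tag_seq, max_mismatch = max_mismatch,
                   min_junction_len = min_junction_len)
    status[has_bc] <- tt$status
    junction[has_bc] <- tt$junction
  }
  pass <- status == "ok"
  position <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  if (any(pass)) {
    mp <- map_junctions(junction[pass], index, max_mismatch = max_mismatch)
    position[pass] <- mp$position
    strand[pass] <- mp$strand
    status[pass] <- mp$status
  }

  report <- list(
    total_reads = n,
    barcode_matched = sum(has_bc),
    tag_matched = sum(has_bc) - sum(status == "tag_mismatch"),
    passed_length_filter = sum(pass),
    mapped_unique = sum(status == "mapped"),
    mapped_ambiguous = sum(status == "ambiguous"),
    unmapped = sum(status == "unmapped"))

  profiles <- lapply(names(barcodes), function(s) {
    keep <- which(status == "mapped" & sample == s)
    tally_profile(data.frame(position = position[keep], strand = strand[keep],
                             stringsAsFactors = FALSE),
                  sample_id = s, replicon_id = index$replicon_id,
                  collapse_strands = collapse_strands)
  })
  names(profiles) <- names(barcodes)

  list(profiles = profiles, report = report,
       assignments = data.frame(read_id = reads$read_id, sample = sample,
                                position = position, strand = strand,
                                status = status, stringsAsFactors = FALSE))
}

#' Ingest mapped junction sites from a SAM file
#'
#' Uses only RNAME/POS/FLAG (plus the read width) of primary mapped records:
#' a forward-strand record reports its leftmost base, a reverse-strand
#' record its rightmost base, matching the first-genomic-base-of-junction
#' convention of [map_junctions()].
#'
#' @param path SAM file path.
#' @return data.frame with `replicon`, `position`, `strand`, one row per
#'   mapped read, suitable for [tally_profile()].
#' @export
read_sam_sites <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "qwidth"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  minus <- x$strand == "-"
  data.frame(replicon = as.character(x$rname),
             position = ifelse(minus, x$pos + x$qwidth - 1L, x$pos),
             strand = ifelse(minus, "-", "+"), stringsAsFactors = FALSE)
}

## --- plain-text IO -------------------------------------------------------

#' Write / read an insertion-site table (TSV)
#'
#' Columns `replicon  position  strand  read_count`, 1-based positions.
#'
#' @param profile a [tn_profile()].
#' @param path file path.
#' @param sample_id sample name used when reading.
#' @return `write_profile` invisibly returns `path`; `read_profile` a
#'   [tn_profile()].
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(replicon = attr(profile, "replicon_id"),
                   position = profile$position, strand = profile$strand,
                   read_count = profile$count)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path, sample_id = basename(path)) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "character",
                                  "integer"))
  tn_profile(df$position, df$strand, df$read_count, sample_id = sample_id,
             replicon_id = if (nrow(df)) df$replicon[1] else "chr")
}

#' Write a processing report as JSON
#' @param report funnel counter list from [process_reads()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
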