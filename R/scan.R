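# Coordinate convention used throughout this module: positions are
# 1-based with the transcription start site as position 1. A "bond" b is
# the phosphodiester bond between residues b and b + 1. "+2" means the
# 2nd nucleotide downstream of the bond (residue b + 2); "-3"/"-4" mean
# the 3rd/4th nucleotides upstream (residues b - 2 and b - 3). The
# literature sometimes counts from the first nucleotide of the
# downstream fragment instead; the bond-based convention here is stated
# wherever coordinates leave the package (BED output is 0-based
# half-open).

validate_rna <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop("`seq` must be a single non-empty string", call. = FALSE)
  }
  s <- chartr("tu", "TU", toupper(seq))
  s <- chartr("T", "U", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "U"))
  if (length(bad)) {
    stop(sprintf("invalid residue '%s' at position %d",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  chars
}

#' Scan an RNA sequence for candidate RNase E cleavage bonds
#'
#' Applies the two sequence rules of the RNase E cleavage signature (the
#' "AU clamp") to every scissile bond of a single-stranded RNA: the +2U
#' rule (uridine at the 2nd nucleotide downstream of the bond) and the
#' -3/4A rule (adenine at the 3rd or 4th nucleotide upstream). Bonds `b`
#' with `3 <= b <= length - 2` are scanned so the +2 and -3 positions
#' exist; the -4 position is checked only where it exists. T is accepted
#' on input and read as U. Only bonds matching at least one rule are
#' returned; bonds matching both rules are listed first.
#'
#' @param seq A single RNA sequence (character string over A/C/G/U,
#'   T tolerated), at least 5 nt.
#' @param id Optional sequence identifier carried into the output.
#' @return A tibble with columns `id`, `bond` (1-based; the bond between
#'   residues `bond` and `bond + 1`), `plus2_u`, `minus34_a`, `both`,
#'   `n_rules`, ordered with `both == TRUE` bonds first, then by
#'   position.
#' @seealso [write_site_bed()], [simulate_sequence_with_sites()].
#' @export
#' @examples
#' scan_cleavage_sites("GGAAGGGUGG")  # AU clamp around bond 6
scan_cleavage_sites <- function(seq, id = "seq1") {
  chars <- validate_rna(seq)
  len <- length(chars)
  if (len < 5L) stop("sequence must be at least 5 nt", call. = FALSE)

  b <- 3:(len - 2L)
  plus2_u <- chars[b + 2L] == "U"
  minus3_a <- chars[b - 2L] == "A"
  minus4_a <- (b - 3L >= 1L) & (chars[pmax(b - 3L, 1L)] == "A")
  minus34_a <- minus3_a | minus4_a
  keep <- plus2_u | minus34_a

  p2 <- plus2_u[keep]
  m34 <- minus34_a[keep]
  tibble::tibble(
    id = id,
    bond = b[keep],
    plus2_u = p2,
    minus34_a = m34,
    both = p2 & m34,
    n_rules = as.integer(p2) + as.integer(m34)
  ) |>
    dplyr::arrange(dplyr::desc(.data$both), .data$bond)
}

#' Find uridine tracts in an RNA sequence
#'
#' Maximal runs of consecutive U residues of at least `min_len`
#' nucleotides — the signature element cleaved by RNase E within the
#' long 5' UTR studied here is a stretch of six consecutive uridines.
#'
#' @param seq A single RNA sequence (T read as U).
#' @param min_len Minimum run length (default 6).
#' @param id Optional sequence identifier.
#' @return A tibble with `id`, `start`, `end` (1-based inclusive) and
#'   `length`, sorted by position; zero rows if no tract qualifies.
#' @export
#' @examples
#' find_u_tracts("AUUUUUUA", min_len = 6)  # 2..7
find_u_tracts <- function(seq, min_len = 6, id = "seq1") {
  if (!is.numeric(min_len) || min_len < 1) {
    stop("`min_len` must be >= 1", call. = FALSE)
  }
  chars <- validate_rna(seq)
  r <- rle(chars == "U")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  tibble::tibble(
    id = id,
    start = starts[keep],
    end = ends[keep],
    length = r$lengths[keep]
  )
}

#' Cluster mapped RNA 3'-end positions into regions
#'
#' Greedy single-linkage clustering in one dimension: positions are
#' sorted and a cluster is extended while the next position lies within
#' `max_gap` nt of the cluster's current maximum. With the default gap
#' of 10 nt, end positions mapped by 3' RACE within the two regions
#' 78–90 and 214–229 nt downstream of the TSS resolve into exactly two
#' clusters.
#'
#' @param positions Positive integer positions (nt downstream of the
#'   TSS), any order, duplicates allowed.
#' @param max_gap Maximum within-cluster gap between neighbouring
#'   positions (default 10).
#' @return A tibble with `start`, `end` (inclusive span) and `count`
#'   (member positions, counting duplicates), sorted by `start`.
#' @export
#' @examples
#' cluster_end_positions(c(78, 82, 90, 214, 220, 229))
cluster_end_positions <- function(positions, max_gap = 10) {
  if (length(positions) == 0L) {
    stop("`positions` must be non-empty", call. = FALSE)
  }
  if (!is.numeric(positions) || any(!is.finite(positions)) ||
      any(positions <= 0) || any(positions != as.integer(positions))) {
    stop("`positions` must be positive integers", call. = FALSE)
  }
  if (!is.numeric(max_gap) || max_gap < 0) {
    stop("`max_gap` must be >= 0", call. = FALSE)
  }
  p <- sort(as.integer(positions))
  new_cluster <- c(TRUE, diff(p) > max_gap)
  cl <- cumsum(new_cluster)
  tibble::tibble(
    start = tapply(p, cl, min) |> as.integer(),
    end = tapply(p, cl, max) |> as.integer(),
    count = tapply(p, cl, length) |> as.integer()
  )
}

#' Read RNA sequences from a FASTA file
#'
#' Multi-record FASTA; T is converted to U and the alphabet validated.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`.
#' @export
read_rna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- vapply(as.character(set), function(s) {
    paste(validate_rna(s), collapse = "")
  }, character(1))
  tibble::tibble(
    id = vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L),
    seq = unname(seqs)
  )
}

#' Write RNA sequences to a FASTA file
#'
#' @param sequences Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(sequences, path, width = 70) {
  stopifnot(all(c("id", "seq") %in% names(sequences)))
  set <- Biostrings::BStringSet(sequences$seq)
  names(set) <- sequences$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write cleavage-site calls as BED-like intervals
#'
#' Emits one 6-column BED line per called bond. On disk the coordinates
#' are 0-based half-open per the BED convention: the interval
#' `[bond - 1, bond + 1)` spans the two residues flanking the scissile
#' bond. The name field lists the matched rules and the score is the
#' number of rules matched. A leading comment line states the
#' convention.
#'
#' @param sites Tibble from [scan_cleavage_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_bed <- function(sites, path) {
  stopifnot(all(c("id", "bond", "plus2_u", "minus34_a", "n_rules")
                %in% names(sites)))
  name <- ifelse(sites$plus2_u & sites$minus34_a, "plus2U;minus34A",
                 ifelse(sites$plus2_u, "plus2U", "minus34A"))
  lines <- c(
    paste0("# BED-like cleavage-bond intervals: 0-based half-open; ",
           "[bond-1, bond+1) spans the residues flanking the bond ",
           "(bond is 1-based internally)"),
    sprintf("%s\t%d\t%d\t%s\t%d\t+",
            sites$id, sites$bond - 1L, sites$bond + 1L, name,
            sites$n_rules)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text list of 3'-end positions
#'
#' One integer per line (1-based, nt downstream of the TSS); blank lines
#' and `#` comments are ignored.
#'
#' @param path Input path.
#' @return Integer vector.
#' @export
read_positions <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vals <- suppressWarnings(as.integer(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("%s: line %d is not an integer position", path, bad),
         call. = FALSE)
  }
  vals
}
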