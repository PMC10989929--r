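test_that("rule matching on hand-enumerable sequences", {
  # no A and no U anywhere: no rule can fire
  expect_equal(nrow(scan_cleavage_sites("CCCCCCCCCC")), 0L)

  # AAUUUUUU: hand enumeration. Bonds 3..6 are scanned; +2 residues are
  # positions 5..8, all U, so every bond matches plus2_u; an upstream A
  # sits at b-2 or b-3 for bonds 3 (pos 1), 4 (pos 2) and 5 (pos 2).
  hits <- scan_cleavage_sites("AAUUUUUU")
  expect_setequal(hits$bond, 3:6)
  expect_true(all(hits$plus2_u))
  expect_equal(sort(hits$bond[hits$minus34_a]), c(3, 4, 5))
  # both-rule bonds come first, each block ordered by position
  expect_equal(hits$bond, c(3, 4, 5, 6))
  expect_equal(hits$both, c(TRUE, TRUE, TRUE, FALSE))

  # T tolerated on input, converted to U
  expect_equal(scan_cleavage_sites("AATTTTTT"), scan_cleavage_sites("AAUUUUUU"))

  expect_error(scan_cleavage_sites("ACGUN"), "position 5")
  expect_error(scan_cleavage_sites("ACGU"), "at least 5")
})

test_that("scanner and U-tract finder match exhaustive brute force on random sequences", {
  for (s in 1:200) {
    seq <- random_rna(100, seed = s)
    got <- scan_cleavage_sites(seq)
    got <- got[order(got$bond), ]
    want <- brute_scan(seq)
    expect_equal(got$bond, want$bond)
    expect_equal(got$plus2_u, want$plus2_u)
    expect_equal(got$minus34_a, want$minus34_a)
    expect_equal(got$both, want$both)

    for (ml in c(2, 4, 6)) {
      got_u <- find_u_tracts(seq, min_len = ml)
      want_u <- brute_u_tracts(seq, min_len = ml)
      expect_equal(got_u$start, want_u$start)
      expect_equal(got_u$end, want_u$end)
    }
  }
})

test_that("U tracts are maximal, sorted and threshold-respecting", {
  expect_equal(find_u_tracts("AUUUUUUA", min_len = 6)$start, 2)
  expect_equal(find_u_tracts("AUUUUUUA", min_len = 6)$end, 7)
  expect_equal(nrow(find_u_tracts("UUUUU", min_len = 6)), 0L)
  expect_error(find_u_tracts("AUU", min_len = 0), "min_len")

  for (s in 1:50) {
    seq <- random_rna(300, seed = 1000 + s)
    tr <- find_u_tracts(seq, min_len = 3)
    if (nrow(tr) == 0) next
    chars <- strsplit(chartr("T", "U", seq), "")[[1]]
    # flanking residues are not U (or the boundary)
    left <- tr$start - 1
    right <- tr$end + 1
    expect_true(all(left < 1 | chars[pmax(left, 1)] != "U"))
    expect_true(all(right > 300 | chars[pmin(right, 300)] != "U"))
    expect_true(all(diff(tr$start) > 0))
    # non-overlapping
    expect_true(all(tr$start[-1] > tr$end[-nrow(tr)] + 1))
  }
})

test_that("end-position clustering reproduces the two mapped 3'-end regions", {
  # 17 mapped ends drawn across the two regions 78-90 and 214-229 nt
  # downstream of the TSS, including the boundary positions
  ends <- c(78, 79, 81, 84, 85, 85, 88, 90, 90,
            214, 216, 220, 221, 224, 226, 228, 229)
  expect_equal(length(ends), 17L)
  cl <- cluster_end_positions(ends, max_gap = 10)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$start, c(78, 214))
  expect_equal(cl$end, c(90, 229))
  expect_equal(cl$count, c(9L, 8L))

  # order invariance
  perm <- withr::with_seed(3, sample(ends))
  expect_equal(cluster_end_positions(perm, max_gap = 10), cl)

  # single position
  expect_equal(cluster_end_positions(42),
               tibble::tibble(start = 42L, end = 42L, count = 1L))

  expect_error(cluster_end_positions(integer(0)), "non-empty")
  expect_error(cluster_end_positions(c(5, -2)), "positive")
})

test_that("cluster count is non-increasing in the gap threshold", {
  pos <- withr::with_seed(9, sort(sample(1:400, 60, replace = TRUE)))
  counts <- vapply(c(0, 1, 2, 5, 10, 20, 50, 400),
                   function(g) nrow(cluster_end_positions(pos, max_gap = g)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 1)
})

test_that("FASTA and BED round trips preserve sequences and calls", {
  tmp <- withr::local_tempdir()
  seqs <- tibble::tibble(
    id = c("utr1", "utr2"),
    seq = c(random_rna(80, seed = 1), random_rna(120, seed = 2))
  )
  fa <- file.path(tmp, "seqs.fasta")
  write_rna_fasta(seqs, fa)
  back <- read_rna_fasta(fa)
  expect_equal(back, seqs)

  # T on disk is read back as U
  writeLines(c(">t", "ACGT"), file.path(tmp, "t.fasta"))
  expect_equal(read_rna_fasta(file.path(tmp, "t.fasta"))$seq, "ACGU")

  sites <- scan_cleavage_sites(seqs$seq[1], id = "utr1")
  bed <- file.path(tmp, "sites.bed")
  write_site_bed(sites, bed)
  lines <- readLines(bed)
  expect_match(lines[1], "^# BED-like")
  fields <- strsplit(lines[-1], "\t")
  # 0-based half-open interval spans the two residues flanking the bond
  expect_equal(as.integer(vapply(fields, `[`, character(1), 2)),
               sites$bond - 1L)
  expect_equal(as.integer(vapply(fields, `[`, character(1), 3)),
               sites$bond + 1L)

  pos_file <- file.path(tmp, "ends.txt")
  writeLines(c("# comment", "78", "90", "", "214"), pos_file)
  expect_equal(read_positions(pos_file), c(78L, 90L, 214L))
  writeLines("notanumber", pos_file)
  expect_error(read_positions(pos_file), "line 1")
})
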