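# ORF scanning on both strands: length convention, N handling, retention rule.

sense <- function(n, codon = "AAA") strrep(codon, n)

test_that("reverse_complement complements, reverses, maps N to N, and is an involution", {
  expect_equal(reverse_complement("ATGC"), "GCAT")
  expect_equal(reverse_complement("AAAN"), "NTTT")
  expect_error(reverse_complement("ATX"), "outside")
  withr::with_seed(11, {
    seqs <- random_dna(200, c(1L, 50L), alphabet = c("A", "C", "G", "T", "N"))
    expect_equal(reverse_complement(reverse_complement(seqs)), seqs)
  })
})

test_that("the minimum coding length counts ATG through the last sense codon, stop excluded", {
  # 40 coding codons (ATG + 39) = 120 nt -> kept
  orfs <- find_orfs(paste0("ATG", sense(39), "TAA"))
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$coding_length_nt, 120L)
  expect_equal(orfs$start, 0L)
  expect_equal(orfs$end, 120L)
  # 39 coding codons = 117 nt -> dropped
  expect_equal(nrow(find_orfs(paste0("ATG", sense(38), "TAA"))), 0L)
  # no ATG at all
  expect_equal(nrow(find_orfs(sense(100))), 0L)
  # reaching the end without a stop emits nothing
  expect_equal(nrow(find_orfs(paste0("ATG", sense(60)))), 0L)
})

test_that("an N triplet kills the current candidate but a later ORF still opens", {
  seq_ <- paste0("ATG", sense(30), "ANA", sense(10), "TAA", "ATG", sense(41), "TGA")
  orfs <- find_orfs(seq_)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$start, 3L * 43L)
  expect_equal(orfs$coding_length_nt, 126L)
})

test_that("only the first ATG after a break opens an ORF (no nested ORFs per stop)", {
  seq_ <- paste0("ATG", sense(5), "ATG", sense(40), "TAA")
  orfs <- find_orfs(seq_)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$start, 0L)
})

test_that("find_orfs matches the brute-force oracle on random sequences", {
  withr::with_seed(101, {
    for (i in 1:120) {
      seq_ <- random_dna(1, c(200L, 1500L), alphabet = c("A", "C", "G", "T", "N", "A", "C", "G", "T"))
      got <- as.data.frame(find_orfs(seq_))
      want <- oracle_find_orfs(seq_)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, info = sprintf("sequence %d", i))
    }
  })
})

test_that("raising the length threshold never adds ORFs (monotonicity)", {
  withr::with_seed(5, {
    for (i in 1:30) {
      seq_ <- random_dna(1, c(500L, 2000L))
      lo <- find_orfs(seq_, 120L)
      hi <- find_orfs(seq_, 240L)
      expect_true(all(hi$coding_length_nt >= 240L))
      key <- function(x) paste(x$frame, x$start, x$end)
      expect_true(all(key(hi) %in% key(lo)))
    }
  })
})

test_that("ORFs never overlap within a frame", {
  withr::with_seed(7, {
    for (i in 1:30) {
      orfs <- find_orfs(random_dna(1, c(1000L, 3000L)), 60L)
      by_frame <- split(orfs, orfs$frame)
      for (fr in by_frame) {
        if (nrow(fr) < 2L) next
        expect_true(all(fr$start[-1] >= fr$end[-nrow(fr)] + 3L))
      }
    }
  })
})

test_that("strand extraction swaps cleanly under reverse complement", {
  withr::with_seed(13, {
    for (i in 1:25) {
      contig <- list(id = "c", sequence = random_dna(1, c(400L, 1500L)))
      flipped <- list(id = "c", sequence = reverse_complement(contig$sequence))
      a <- strand_orfs(contig, 60L)
      b <- strand_orfs(flipped, 60L)
      cols <- c("frame", "start", "end", "coding_length_nt")
      expect_equal(
        as.data.frame(a[a$strand == "forward", cols]),
        as.data.frame(b[b$strand == "reverse", cols]),
        ignore_attr = TRUE
      )
      expect_equal(
        as.data.frame(a[a$strand == "reverse", cols]),
        as.data.frame(b[b$strand == "forward", cols]),
        ignore_attr = TRUE
      )
    }
  })
})

test_that("a palindromic contig yields identical ORF lists on both strands", {
  half <- paste0("ATG", sense(40, "AAC"), "TAA")
  contig <- list(id = "p", sequence = paste0(half, reverse_complement(half)))
  orfs <- strand_orfs(contig)
  cols <- c("frame", "start", "end")
  expect_equal(
    as.data.frame(orfs[orfs$strand == "forward", cols]),
    as.data.frame(orfs[orfs$strand == "reverse", cols]),
    ignore_attr = TRUE
  )
})

test_that("the retention rule keeps each strand independently", {
  orf_row <- function(strand, start) {
    tibble::tibble(
      contig_id = "c1", strand = strand, frame = 0L,
      start = start, end = start + 120L, coding_length_nt = 120L
    )
  }
  # forward 2, reverse 0 -> forward kept
  two_fwd <- dplyr::bind_rows(orf_row("forward", 0L), orf_row("forward", 200L))
  kept <- retain_strand_samples(two_fwd)
  expect_equal(unique(kept$strand), "forward")
  # one per strand -> contig discarded
  one_each <- dplyr::bind_rows(orf_row("forward", 0L), orf_row("reverse", 0L))
  expect_equal(nrow(retain_strand_samples(one_each)), 0L)
  # both strands qualify -> both kept
  both <- dplyr::bind_rows(
    orf_row("forward", 0L), orf_row("forward", 200L),
    orf_row("reverse", 0L), orf_row("reverse", 200L)
  )
  expect_setequal(unique(retain_strand_samples(both)$strand), c("forward", "reverse"))
})
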