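test_that("telomere arrays are counted at both termini", {
  set.seed(7)
  mid <- paste(sample(c("A", "C"), 400, replace = TRUE), collapse = "")
  seq <- paste0(strrep("CCCTAA", 7), "GGGGGG", mid, "AAAAAA", strrep("TTAGGG", 4))
  calls <- detect_telomeres(tibble::tibble(chrom = "c1", sequence = seq))
  expect_equal(calls$tandem_copies[calls$terminus == "5prime"], 7L)
  expect_equal(calls$tandem_copies[calls$terminus == "3prime"], 4L)
  expect_true(all(calls$present))

  flat <- detect_telomeres(tibble::tibble(chrom = "c1", sequence = mid))
  expect_equal(flat$tandem_copies, c(0L, 0L))
  expect_false(any(flat$present))

  expect_error(detect_telomeres(tibble::tibble(chrom = "c1", sequence = "ACG")),
               class = "mycomine_validation_error")
})

test_that("reverse-complementing a chromosome swaps the terminal calls", {
  for (s in c(1, 9)) {
    sim <- simulate_genome(genome_sim_spec(seed = s, n_chromosomes = 2))
    fwd <- detect_telomeres(sim$chromosomes)
    rev <- detect_telomeres(sim$chromosomes |>
                              dplyr::mutate(sequence = revcomp(sequence)))
    for (ch in sim$chromosomes$chrom) {
      f <- fwd[fwd$chrom == ch, ]
      r <- rev[rev$chrom == ch, ]
      expect_equal(r$tandem_copies[r$terminus == "5prime"],
                   f$tandem_copies[f$terminus == "3prime"])
      expect_equal(r$tandem_copies[r$terminus == "3prime"],
                   f$tandem_copies[f$terminus == "5prime"])
    }
  }
})

test_that("simulated telomere copy numbers are recovered exactly", {
  telo <- cbind(c(7L, 3L), c(4L, 9L))
  sim <- simulate_genome(genome_sim_spec(seed = 21, n_chromosomes = 2,
                                         telomere_copies = telo))
  calls <- detect_telomeres(sim$chromosomes)
  expect_equal(calls$tandem_copies[calls$terminus == "5prime"], telo[, 1])
  expect_equal(calls$tandem_copies[calls$terminus == "3prime"], telo[, 2])
})

test_that("centromere candidate is the longest ORF-free interval", {
  g <- tibble::tibble(
    gene_id = c("a", "b"), chrom = "c1", start = c(1L, 901L),
    end = c(100L, 1000L), strand = "+", kind = "protein_coding",
    length_nt = 100L
  )
  lens <- tibble::tibble(chrom = "c1", length = 1000L)
  cand <- find_centromere_candidates(g, chrom_lengths = lens)
  expect_equal(c(cand$start, cand$end, cand$length), c(101, 901 - 1, 800))

  # two equal-length internal gaps: leftmost wins
  g3 <- tibble::tibble(
    gene_id = c("a", "b", "c"), chrom = "c1",
    start = c(1L, 301L, 601L), end = c(100L, 400L, 700L),
    strand = "+", kind = "protein_coding", length_nt = 100L
  )
  cand3 <- find_centromere_candidates(g3, chrom_lengths =
                                        tibble::tibble(chrom = "c1", length = 750L))
  expect_equal(c(cand3$start, cand3$end), c(101, 300))

  nc <- g; nc$kind <- "tRNA"
  expect_error(find_centromere_candidates(nc, chrom_lengths = lens),
               class = "mycomine_validation_error")
})

test_that("planted centromeres are recovered with exact repeat and expression evidence", {
  for (s in c(4, 23)) {
    sim <- simulate_genome(genome_sim_spec(seed = s))
    cand <- find_centromere_candidates(
      sim$genes, filter_repeat_hits(sim$repeats), sim$expr_track,
      sim$chromosomes[c("chrom", "length")], window = sim$expr_window
    )
    truth <- sim$truth$centromeres
    expect_equal(cand$start, truth$start)
    expect_equal(cand$end, truth$end)
    expect_equal(cand$rt_fraction, truth$rt_fraction, tolerance = 1e-12)
    expect_equal(cand$expr_ratio, truth$expr_ratio)
    expect_true(all(cand$rt_dominant))

    # validator: no protein-coding overlap, and no larger ORF-free gap exists
    pc <- sim$genes[sim$genes$kind == "protein_coding", ]
    for (k in seq_len(nrow(cand))) {
      on_chr <- pc[pc$chrom == cand$chrom[k], ]
      expect_false(any(on_chr$start <= cand$end[k] & on_chr$end >= cand$start[k]))
      gaps <- sort(on_chr$start)[-1] - sort(on_chr$end)[-nrow(on_chr)] - 1L
      expect_true(all(cand$length[k] >= gaps))
    }
  }
})

test_that("mitogenome comparison recovers planted differences and matches a full-matrix reference", {
  mp <- simulate_mito_pair(length = 8000L, n_substitutions = 7,
                           n_deletions = 1, deletion_length = 3, seed = 3)
  res <- mito_compare(mp$seq_a, mp$seq_b, circular = FALSE)
  expect_equal(res$substitutions, 7)
  expect_equal(res$insertions, 0)
  expect_equal(res$deletions, 3)
  ref <- adist(mp$seq_a, mp$seq_b, counts = TRUE)
  expect_equal(res$distance, ref[1, 1])
  cnt <- attr(ref, "counts")
  expect_equal(res$substitutions, as.numeric(cnt[, , "sub"]))
  expect_equal(res$deletions + res$insertions,
               as.numeric(cnt[, , "del"] + cnt[, , "ins"]))

  ident <- mito_compare(mp$seq_a, mp$seq_a, circular = FALSE)
  expect_equal(ident$distance, 0L)
  expect_equal(ident$per_base_rate, 0)
})

test_that("substitution counts are symmetric and indels swap under argument exchange", {
  mp <- simulate_mito_pair(length = 5000L, n_substitutions = 4, n_deletions = 2,
                           deletion_length = 2, n_insertions = 1,
                           insertion_length = 3, seed = 12)
  ab <- mito_compare(mp$seq_a, mp$seq_b, circular = FALSE)
  ba <- mito_compare(mp$seq_b, mp$seq_a, circular = FALSE)
  expect_equal(ab$substitutions, ba$substitutions)
  expect_equal(ab$insertions, ba$deletions)
  expect_equal(ab$deletions, ba$insertions)
  expect_equal(ab$distance, ba$distance)
})

test_that("the band must cover the length difference", {
  expect_error(mito_compare(strrep("A", 300), strrep("A", 200), band = 5,
                            circular = FALSE),
               class = "mycomine_validation_error")
})

test_that("circular rotation is canonicalised before comparison", {
  mp <- simulate_mito_pair(length = 6000L, n_substitutions = 2, seed = 8)
  rot <- paste0(substr(mp$seq_b, 1501, 6000), substr(mp$seq_b, 1, 1500))
  res <- mito_compare(mp$seq_a, rot, circular = TRUE)
  expect_equal(res$substitutions, 2)
  expect_equal(res$distance, 2L)
})

test_that("display arithmetic reproduces the per-base error bound convention", {
  expect_equal(per_base_rate(1, 115207), 8.68e-06)
  expect_equal(per_base_rate(0, 100), 0)
})

test_that("copy ratio recovers planted amplification and respects invariances", {
  tr <- coverage_track("c1", rep(10, 100))
  iv <- function(s, e) tibble::tibble(chrom = "c1", start = s, end = e)
  expect_equal(copy_ratio(tr, iv(1L, 10000L), iv(50001L, 100000L), 1000L), 1)

  tr2 <- coverage_track("c1", c(rep(214, 50), rep(10, 50)))
  expect_equal(copy_ratio(tr2, iv(1L, 50000L), iv(50001L, 100000L), 1000L), 21.4)

  dt <- simulate_depth_track(fold = 38, seed = 6)
  est <- copy_ratio(dt$track, dt$target_intervals, dt$single_copy_intervals,
                    dt$window)
  expect_lt(abs(est - 38) / 38, 0.05)
  # invariant under uniform scaling of the whole track
  scaled <- dt$track; scaled$depth <- scaled$depth * 3.7
  expect_equal(copy_ratio(scaled, dt$target_intervals,
                          dt$single_copy_intervals, dt$window), est)

  zero <- coverage_track("c1", rep(0, 100))
  expect_error(copy_ratio(zero, iv(1L, 1000L), iv(2001L, 3000L), 1000L),
               class = "mycomine_validation_error")
})
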