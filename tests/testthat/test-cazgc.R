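test_that("intergenic gap counts equal rank distance and brute-force gap walks", {
  g <- mk_genes(10)
  expect_equal(intergenic_gap_count(g, "c1_g05", "c1_g06"), 1L)
  expect_equal(intergenic_gap_count(g, "c1_g05", "c1_g05"), 0L)
  # brute force: count gene boundaries crossed walking rank 3 -> rank 8
  ranked <- gene_ranks(g)
  walked <- sum(ranked$rank > 3 & ranked$rank <= 8)
  expect_equal(intergenic_gap_count(g, "c1_g03", "c1_g08"), walked)
  expect_equal(walked, 5L)
  expect_equal(intergenic_gap_count(g, "c1_g08", "c1_g03"), 5L)  # symmetric

  g2 <- mk_genes(3, chrom = "c2")
  expect_error(intergenic_gap_count(dplyr::bind_rows(g, g2), "c1_g01", "c2_g01"),
               class = "mycomine_validation_error")
})

test_that("membership rules fire exactly as stated on forced configurations", {
  g <- mk_genes(10)
  # no CAZyme genes at all -> nothing can be called
  expect_equal(nrow(predict_cazgc(g, mk_signatures(g, rep("other", 10)))), 0L)

  # three adjacent CAZymes -> one cluster of three
  roles <- rep("other", 10); roles[3:5] <- "cazyme"
  cl <- predict_cazgc(g, mk_signatures(g, roles))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_cazyme, 3L)
  expect_equal(cl$n_signature, 0L)
  expect_equal(cl$members[[1]], g$gene_id[3:5])
  expect_equal(cl$start, g$start[3])
  expect_equal(cl$end, g$end[5])

  # two CAZymes with a transporter between them -> cluster via signature rule
  roles <- rep("other", 10); roles[c(3, 5)] <- "cazyme"; roles[4] <- "transporter"
  cl <- predict_cazgc(g, mk_signatures(g, roles))
  expect_equal(nrow(cl), 1L)
  expect_equal(c(cl$n_cazyme, cl$n_signature), c(2L, 1L))

  # the same pair without the transporter -> below membership threshold
  roles[4] <- "other"
  expect_equal(nrow(predict_cazgc(g, mk_signatures(g, roles))), 0L)

  # two CAZymes three gaps apart never link: g3 stays outside the cluster
  # formed by the adjacent run at 6-8
  roles <- rep("other", 10); roles[c(3, 6, 7, 8)] <- "cazyme"
  cl <- predict_cazgc(g, mk_signatures(g, roles))
  expect_equal(members_set(cl), list(sort(g$gene_id[6:8])))
})

test_that("a signature gene bridges two CAZymes through transitive linkage", {
  g <- mk_genes(9)
  roles <- rep("other", 9); roles[c(2, 6)] <- "cazyme"; roles[4] <- "transporter"
  cl <- predict_cazgc(g, mk_signatures(g, roles))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$members[[1]], g$gene_id[c(2, 4, 6)])
})

test_that("unknown gene ids in the signature table are rejected", {
  g <- mk_genes(5)
  sig <- tibble::tibble(gene_id = "ghost", role = "cazyme")
  expect_error(predict_cazgc(g, sig), class = "mycomine_validation_error")
  expect_equal(nrow(predict_cazgc(g[0, ], g[0, "gene_id"] |>
                                    dplyr::mutate(role = character(0)))), 0L)
})

test_that("dual CAZyme/transporter tags count once, as CAZyme", {
  g <- mk_genes(6)
  sig <- tibble::tibble(
    gene_id = c("c1_g02", "c1_g03", "c1_g03"),
    role = c("cazyme", "cazyme", "transporter")
  )
  cl <- predict_cazgc(g, sig)
  # two CAZymes, no independent signature gene -> no cluster
  expect_equal(nrow(cl), 0L)
})

test_that("cluster caller matches the brute-force reference on random instances", {
  for (s in 1:300) {
    inst <- simulate_cazgc_instance(n_genes = sample(4:20, 1), seed = s)
    fast <- predict_cazgc(inst$genes, inst$signatures)
    slow <- cazgc_oracle(inst$genes, inst$signatures)
    expect_identical(members_set(fast), members_set(slow))
    expect_identical(fast[c("cluster_id", "chrom", "start", "end")],
                     slow[c("cluster_id", "chrom", "start", "end")])
  }
})

test_that("planted clusters are recovered and decoys rejected on simulated genomes", {
  for (s in c(2, 17, 31)) {
    sim <- simulate_genome(genome_sim_spec(seed = s))
    cl <- predict_cazgc(sim$genes, sim$signatures)
    truth <- sim$truth$clusters
    planted <- truth$members[truth$type == "cluster"]
    expect_equal(members_set(cl), unname(lapply(planted, sort)))
    decoy_genes <- unlist(truth$members[truth$type == "decoy"])
    expect_false(any(decoy_genes %in% unlist(cl$members)))
    v <- validate_cazgc(cl, sim$genes, sim$signatures)
    expect_true(all(v$valid))
  }
})

test_that("adding a CAZyme inside a cluster span never shrinks the cluster", {
  for (s in 1:40) {
    inst <- simulate_cazgc_instance(n_genes = 15, seed = s)
    before <- predict_cazgc(inst$genes, inst$signatures)
    if (nrow(before) == 0L) next
    ranked <- gene_ranks(inst$genes)
    span_genes <- ranked[ranked$start >= before$start[1] &
                           ranked$end <= before$end[1], ]
    extra <- setdiff(span_genes$gene_id, c(inst$signatures$gene_id))
    if (length(extra) == 0L) next
    sig2 <- dplyr::bind_rows(inst$signatures,
                             tibble::tibble(gene_id = extra[1], role = "cazyme"))
    after <- predict_cazgc(inst$genes, sig2)
    grown <- after$members[vapply(after$members, function(m)
      all(before$members[[1]] %in% m), logical(1))]
    expect_length(grown, 1L)
  }
})

test_that("calls are invariant under gene relabeling and coordinate reversal", {
  inst <- simulate_cazgc_instance(n_genes = 16, seed = 77)
  base <- predict_cazgc(inst$genes, inst$signatures)

  relab <- setNames(sprintf("x%02d", seq_len(nrow(inst$genes))), inst$genes$gene_id)
  g2 <- inst$genes; g2$gene_id <- unname(relab[g2$gene_id])
  s2 <- inst$signatures; s2$gene_id <- unname(relab[s2$gene_id])
  cl2 <- predict_cazgc(g2, s2)
  expect_identical(members_set(cl2),
                   lapply(base$members, function(m) sort(unname(relab[m]))))

  L <- max(inst$genes$end) + 100L
  g3 <- inst$genes
  new_start <- L - g3$end + 1L
  g3$end <- L - g3$start + 1L
  g3$start <- new_start
  g3$rank <- NULL
  cl3 <- predict_cazgc(g3, inst$signatures)
  expect_identical(members_set(cl3), members_set(base))
})

test_that("benchmark mode tallies predicted clusters per genome", {
  sims <- lapply(c(3, 8), function(s) simulate_genome(genome_sim_spec(seed = s)))
  genomes <- lapply(sims, function(s) list(genes = s$genes, signatures = s$signatures))
  names(genomes) <- c("simA", "simB")
  out <- withr::local_tempfile(fileext = ".tsv")
  res <- benchmark_cazgc(genomes, out = out)
  truth_counts <- vapply(sims, function(s)
    sum(s$truth$clusters$type == "cluster"), integer(1))
  expect_equal(res$n_clusters, truth_counts)
  expect_true(file.exists(out))
  # empty signature table -> zero clusters
  empty <- benchmark_cazgc(list(z = list(
    genes = sims[[1]]$genes,
    signatures = tibble::tibble(gene_id = character(), role = character()))))
  expect_equal(empty$n_clusters, 0L)
})
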