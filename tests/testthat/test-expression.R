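test_that("RPK and FPKM follow their unit definitions", {
  expect_equal(rpk(100, 1000), 100)
  expect_equal(rpk(0, 1000), 0)
  expect_equal(rpk(250, 2500), 100)
  expect_error(rpk(10, 0), class = "mycomine_validation_error")
  expect_equal(fpkm(10, 1000, 1e7), 1)
  expect_equal(fpkm(0, 1000, 1e7), 0)
  expect_equal(fpkm(37, 1850, 2e6), 10)
})

test_that("TPM normalisation forces column sums of one million", {
  single <- tibble::tibble(gene_id = "g1", length_nt = 700L, s1 = 17L)
  expect_equal(tpm(single)$s1, 1e6)

  equal_rpk <- tibble::tibble(gene_id = paste0("g", 1:4),
                              length_nt = c(1000L, 2000L, 500L, 250L),
                              s1 = c(10L, 20L, 5L, 2.5))
  expect_equal(tpm(equal_rpk)$s1, rep(2.5e5, 4))

  # 5x3 fixture against an explicit spreadsheet-style recomputation
  set.seed(10)
  cm <- tibble::tibble(gene_id = paste0("g", 1:5),
                       length_nt = sample(500:3000, 5))
  for (s in c("a", "b", "c")) cm[[s]] <- sample(0:500, 5)
  got <- tpm(cm)
  for (s in c("a", "b", "c")) {
    r <- numeric(5)
    for (i in 1:5) r[i] <- cm[[s]][i] / (cm$length_nt[i] / 1000)
    expect_equal(got[[s]], r / sum(r) * 1e6, tolerance = 1e-9)
    expect_equal(sum(got[[s]]), 1e6, tolerance = 1e-6)
  }
  # all-zero column stays all zero
  cm$z <- 0L
  expect_equal(tpm(cm)$z, rep(0, 5))
})

test_that("Fisher exact p-values match hypergeometric enumeration", {
  expect_equal(fisher_exact_de(5, 95, 5, 95), 1)
  expect_equal(fisher_exact_de(0, 10, 10, 0), fisher_enum_oracle(0, 10, 10, 0),
               tolerance = 1e-14)
  set.seed(3)
  for (i in 1:200) {
    a <- sample(0:30, 1); ra <- sample(0:30, 1)
    b <- sample(0:30, 1); rb <- sample(0:30, 1)
    expect_equal(fisher_exact_de(a, ra, b, rb), fisher_enum_oracle(a, ra, b, rb),
                 tolerance = 1e-12)
  }
})

test_that("Fisher p-values agree with the stats::fisher.test reference", {
  set.seed(4)
  for (i in 1:60) {
    tab <- matrix(sample(0:40, 4, replace = TRUE), 2)
    if (sum(tab[, 1]) == 0 || sum(tab) == 0) next
    mine <- fisher_exact_de(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(mine, fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment equals the direct step-up formula and its invariants", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.01, 0.02, 0.04, 0.9)
  expect_equal(bh_fdr(p), bh_direct_oracle(p))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_direct_oracle(p))
    expect_true(all(adj >= p - 1e-15))
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), adj[perm])
  }
  expect_error(bh_fdr(c(0.2, 1.4)), class = "mycomine_validation_error")
})

mk_deg_fixture <- function(target_a, target_b, target_len = 1000L,
                           n_bg = 400L, bg_count = 1000L) {
  cm <- tibble::tibble(
    gene_id = c("target", paste0("bg", seq_len(n_bg))),
    length_nt = c(target_len, rep(1000L, n_bg)),
    a1 = c(target_a, rep(bg_count, n_bg)),
    a2 = c(target_a, rep(bg_count, n_bg)),
    b1 = c(target_b, rep(bg_count, n_bg)),
    b2 = c(target_b, rep(bg_count, n_bg))
  )
  groups <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2"),
                           group = c("A", "A", "B", "B"))
  list(counts = cm, groups = groups)
}

test_that("the TPM floor silences genes below background expression", {
  # a strongly changed gene whose TPM stays < 0.5 in both groups
  fx <- mk_deg_fixture(target_a = 150L, target_b = 15L, target_len = 1000000L)
  res <- tidy(call_deg(fx$counts, fx$groups, "A", "B"))
  tg <- res[res$gene_id == "target", ]
  expect_lt(max(tg$mean_tpm_a, tg$mean_tpm_b), 0.5)
  expect_lt(tg$fdr, 0.05)           # highly significant...
  expect_gt(tg$fold_change, 3)      # ...and above the fold threshold...
  expect_equal(tg$call, "ns")       # ...yet silenced by the floor
})

test_that("a planted ten-fold gene with deep counts is called up", {
  fx <- mk_deg_fixture(target_a = 5000L, target_b = 500L)
  ct <- call_deg(fx$counts, fx$groups, "A", "B")
  res <- tidy(ct)
  expect_equal(res$call[res$gene_id == "target"], "up")
  g <- glance(ct)
  expect_equal(g$n_up, 1L)
  # zero-vs-nonzero: infinite fold change passes with the floor as guard
  fx0 <- mk_deg_fixture(target_a = 5000L, target_b = 0L)
  res0 <- tidy(call_deg(fx0$counts, fx0$groups, "A", "B"))
  expect_equal(res0$call[res0$gene_id == "target"], "up")
})

test_that("swapping the contrast maps up calls onto down calls exactly", {
  sc <- simulate_counts(expr_sim_spec(seed = 9, n_genes = 300, n_up = 15))
  ab <- tidy(call_deg(sc$counts, sc$groups, "FB", "mono_mycelium"))
  ba <- tidy(call_deg(sc$counts, sc$groups, "mono_mycelium", "FB"))
  expect_identical(ab$gene_id[ab$call == "up"], ba$gene_id[ba$call == "down"])
  expect_identical(ab$gene_id[ab$call == "down"], ba$gene_id[ba$call == "up"])
})

test_that("planted differential expression is recovered at the stated rates", {
  sc <- simulate_counts(expr_sim_spec(seed = 101))
  res <- tidy(call_deg(sc$counts, sc$groups, "FB", "mono_mycelium"))
  up <- res$gene_id[res$call == "up"]
  truth <- sc$truth$gene_id[sc$truth$planted]
  sens <- mean(truth %in% up)
  false_rate <- sum(!up %in% truth) / sum(!sc$truth$planted)
  expect_gte(sens, 0.9)
  expect_lte(false_rate, 0.05)
})

test_that("fruiting-related genes require up-calls in both contrasts by default", {
  # deep, low-dispersion fixture: planted set is recovered exactly
  sc <- simulate_counts(expr_sim_spec(seed = 31, n_genes = 500, n_up = 30,
                                      fold = 10, dispersion = 0.02,
                                      base_meanlog = log(500),
                                      base_sdlog = 0.5))
  c_mono <- call_deg(sc$counts, sc$groups, "FB", "mono_mycelium")
  c_di <- call_deg(sc$counts, sc$groups, "FB", "di_mycelium")
  frg <- classify_frg(c_mono, c_di)
  expect_setequal(frg, sc$truth$gene_id[sc$truth$planted])

  either <- classify_frg(c_mono, c_di, require_both = FALSE)
  expect_true(all(frg %in% either))

  # a gene up only vs monokaryons is excluded under the default conjunction
  only_mono <- setdiff(tidy(c_mono)$gene_id[tidy(c_mono)$call == "up"],
                       tidy(c_di)$gene_id[tidy(c_di)$call == "up"])
  expect_false(any(only_mono %in% frg))
  expect_true(all(only_mono %in% either))
})

test_that("ortholog-overlap classification is an exhaustive disjoint partition", {
  hits <- tibble::tibble(
    query = c("q2", "q3", "q3", "q4", "q5"),
    subject = c("FBIG1", "FBIG1", "FBDG1", "FBDG1", "OTHER1"),
    e_value = c(1e-20, 1e-20, 1e-30, 1e-9, 1e-12)
  )
  cls <- venn_classes(paste0("q", 1:5), hits, "FBIG1", "FBDG1", e_cut = 1e-5)
  expect_equal(as.character(cls$class),
               c("species_specific",   # q1: no hit at all
                 "fbig_ortholog",      # q2
                 "fbig_ortholog",      # q3: hits both, FBIG precedence
                 "fbdg_ortholog",      # q4
                 "other_ortholog"))    # q5: hit outside both sets
  expect_equal(sum(table(cls$class)), 5L)

  fx <- simulate_ortholog_fixture(n_genes = 600, seed = 19)
  got <- venn_classes(fx$frg_ids, fx$hits, fx$fbig_ids, fx$fbdg_ids)
  expect_identical(got$class, fx$truth$class)
})

test_that("reference-set coverage arithmetic matches the printed convention", {
  mk <- function(n) tibble::tibble(query = paste0("q", seq_len(n)),
                                   subject = sprintf("FB%04d", seq_len(n)),
                                   e_value = 1e-20)
  expect_equal(fbig_coverage(mk(254), sprintf("FB%04d", 1:666)),
               tibble::tibble(count = 254L, percent = 38.1))
  expect_equal(fbig_coverage(mk(123), sprintf("FB%04d", 1:500))$percent, 24.6)
  none <- fbig_coverage(mk(0), sprintf("FB%04d", 1:100))
  expect_equal(c(none$count, none$percent), c(0, 0))
  # hits above the cutoff do not count
  weak <- mk(10); weak$e_value <- 1e-3
  expect_equal(fbig_coverage(weak, sprintf("FB%04d", 1:100))$count, 0L)
})
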