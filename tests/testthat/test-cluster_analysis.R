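hox10 <- sprintf("Hox%02d", 1:10)

test_that("cluster detection respects both gap bounds and reports singletons", {
  nk <- sprintf("NK%02d", 1:6)
  # six members within 1 Mb on one chromosome -> one 6-member cluster
  genes <- mk_genes("c1", c(nk[1:3], "other", nk[4:6]), step = 150000L)
  g <- species_genome("s", genes)
  cl <- detect_clusters(g, nk)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]$members), 6L)

  # two members 50 Mb apart -> two singleton clusters
  genes2 <- rbind(mk_genes("c1", nk[1]),
                  mk_genes("c1", nk[2], start0 = 50e6, ids = "far"))
  cl2 <- detect_clusters(species_genome("s", genes2), nk)
  expect_length(cl2, 2L)
  expect_true(all(vapply(cl2, function(x) nrow(x$members), 1L) == 1L))

  # more than max_gap_genes intervening genes split the run
  genes3 <- rbind(mk_genes("c1", nk[1], ids = "m1"),
                  mk_genes("c1", rep("bg", 11), start0 = 100000L,
                           ids = sprintf("bg%02d", 1:11)),
                  mk_genes("c1", nk[2], start0 = 1300000L, ids = "m2"))
  cl3 <- detect_clusters(species_genome("s", genes3), nk,
                         max_gap_genes = 10, max_gap_bp = 5e6)
  expect_length(cl3, 2L)
})

test_that("detection agrees with the adjacency-component oracle on random layouts", {
  set.seed(2024)
  tpl <- sprintf("T%02d", 1:6)
  for (rep in 1:100) {
    n <- sample(5:25, 1)
    genes <- data.frame(
      gene_id = sprintf("g%03d", 1:n),
      chromosome_id = sample(c("c1", "c2"), n, replace = TRUE),
      start = 0L, end = 0L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      family_id = sample(c(tpl, "bg1", "bg2"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    genes <- genes[order(genes$chromosome_id), ]
    for (ch in unique(genes$chromosome_id)) {
      k <- sum(genes$chromosome_id == ch)
      genes$start[genes$chromosome_id == ch] <-
        cumsum(c(0L, sample(c(50000L, 400000L, 6e6), k - 1, replace = TRUE)))
    }
    genes$end <- genes$start + 2000L
    g <- species_genome("s", genes)
    gg <- sample(0:3, 1); gb <- sample(c(1e6, 5e6), 1)
    got <- detect_clusters(g, tpl, max_gap_genes = gg, max_gap_bp = gb)
    got_sets <- lapply(got, function(x) sort(x$members$gene_id))
    got_sets <- got_sets[order(vapply(got_sets, `[`, "", 1))]
    expect_identical(got_sets, oracle_clusters(g, tpl, gg, gb))
  }
})

test_that("detection is independent of gene input order", {
  set.seed(99)
  genes <- mk_genes("c1", sample(c(hox10, "bg")), step = 200000L)
  g1 <- detect_clusters(species_genome("s", genes), hox10)
  g2 <- detect_clusters(species_genome("s", genes[sample(nrow(genes)), ]),
                        hox10)
  expect_identical(g1, g2)
})

test_that("integrity scores match the worked examples", {
  # full canonical cluster, uniform strand -> (1, 1, 1)
  full <- species_genome("s", mk_genes("c1", hox10, step = 100000L))
  sc <- score_integrity(detect_clusters(full, hox10)[[1]], hox10)
  expect_equal(sc$completeness, 1.0)
  expect_equal(sc$order_score, 1.0)
  expect_equal(sc$orientation_score, 1.0)

  # missing Hox03 and Hox06 ("Hox3 and ftz"), remaining 8 in order
  degen <- species_genome("s", mk_genes("c1", hox10[-c(3, 6)],
                                        step = 100000L))
  sc2 <- score_integrity(detect_clusters(degen, hox10)[[1]], hox10)
  expect_equal(sc2$completeness, 0.8)
  expect_equal(sc2$order_score, 1.0)

  # canonical [1..6] observed as [3,1,2,6,4,5] -> LCS 4 -> 4/6
  six <- sprintf("S%d", 1:6)
  obs <- species_genome("s", mk_genes("c1", six[c(3, 1, 2, 6, 4, 5)],
                                      step = 100000L))
  sc3 <- score_integrity(detect_clusters(obs, six)[[1]], six)
  expect_equal(sc3$order_score, 4 / 6)

  # HRO-style reordering: canonical H-R-O observed R-H-O -> 2/3
  hro <- c("Hbn", "Rax", "Otp")
  rho <- species_genome("s", mk_genes("c1", c("Rax", "Hbn", "Otp"),
                                      step = 100000L))
  sc4 <- score_integrity(detect_clusters(rho, hro)[[1]], hro)
  expect_equal(sc4$order_score, 2 / 3)

  expect_error(score_integrity(list(members = NULL), hox10), "empty")
})

test_that("order score is invariant to whole-cluster inversion and LCS matches brute force", {
  brute_lcs <- function(a, b) {
    # longest subsequence of a that is also a subsequence of b
    best <- 0L
    n <- length(a)
    for (mask in 0:(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      sub <- a[idx]
      j <- 1
      for (x in b) if (j <= length(sub) && x == sub[j]) j <- j + 1
      if (j == length(sub) + 1) best <- max(best, length(sub))
    }
    best
  }
  set.seed(7)
  six <- sprintf("S%d", 1:6)
  for (rep in 1:25) {
    ord <- sample(six, sample(3:6, 1))
    g <- species_genome("s", mk_genes("c1", ord, step = 100000L))
    cl <- score_integrity(detect_clusters(g, six)[[1]], six)
    expect_equal(cl$order_score,
                 max(brute_lcs(ord, six), brute_lcs(rev(ord), six)) /
                   length(ord))
    ginv <- species_genome("s", mk_genes("c1", rev(ord), step = 100000L,
                                         strand = "-"))
    clinv <- score_integrity(detect_clusters(ginv, six)[[1]], six)
    expect_equal(clinv$order_score, cl$order_score)
  }
})

test_that("completeness never drops when adding a member; shuffling hurts order on average", {
  set.seed(8)
  six <- sprintf("S%d", 1:6)
  for (k in 2:5) {
    a <- score_integrity(
      detect_clusters(species_genome("s", mk_genes("c1", six[1:k],
                                                   step = 1e5)), six)[[1]],
      six)
    b <- score_integrity(
      detect_clusters(species_genome("s", mk_genes("c1", six[1:(k + 1)],
                                                   step = 1e5)), six)[[1]],
      six)
    expect_gte(b$completeness, a$completeness)
  }
  shuffled <- replicate(200, {
    ord <- sample(six)
    score_integrity(detect_clusters(
      species_genome("s", mk_genes("c1", ord, step = 1e5)), six)[[1]],
      six)$order_score
  })
  expect_lt(mean(shuffled), 1)
})

test_that("ohnologous cluster pairing labels the more intact copy and reports asymmetry", {
  six <- sprintf("S%d", 1:6)
  gA <- mk_genes("c1", six, step = 1e5, ids = paste0("a", 1:6))
  gB <- mk_genes("c2", six[-c(2, 5)], step = 1e5, ids = paste0("b", 1:4))
  g <- species_genome("s", rbind(gA, gB))
  cls <- lapply(detect_clusters(g, six), score_integrity,
                canonical_order = six)
  ohno <- data.frame(gene_a = paste0("a", c(1, 3, 4, 6)),
                     gene_b = paste0("b", 1:4))
  pr <- pair_ohnologous_clusters(cls, ohno)
  expect_length(pr$pairs, 1L)
  p <- pr$pairs[[1]]
  expect_equal(p$more_intact, "A")
  expect_equal(p$cluster_a$chromosome_id, "c1")  # the intact copy
  expect_equal(p$delta_completeness, 2 / 6, tolerance = 1e-12)
  # convention flip: intact copy labelled B
  prB <- pair_ohnologous_clusters(cls, ohno, intact_label = "B")
  expect_equal(prB$pairs[[1]]$more_intact, "B")
  expect_equal(prB$pairs[[1]]$cluster_a$chromosome_id, "c1")

  # identical twins: delta 0, label tie-break by chromosome id
  gB2 <- mk_genes("c2", six, step = 1e5, ids = paste0("c", 1:6))
  g2 <- species_genome("s", rbind(gA, gB2))
  cls2 <- lapply(detect_clusters(g2, six), score_integrity,
                 canonical_order = six)
  ohno2 <- data.frame(gene_a = paste0("a", 1:6), gene_b = paste0("c", 1:6))
  p2 <- pair_ohnologous_clusters(cls2, ohno2)$pairs[[1]]
  expect_equal(p2$delta_completeness, 0)
  expect_equal(p2$cluster_a$chromosome_id, "c1")
})

test_that("the more intact label matches the copy with fewer simulated losses", {
  set.seed(1234)
  six <- sprintf("S%d", 1:6)
  hits <- replicate(100, {
    n_loss <- sample(1:3, 1)
    keep <- sort(sample(6, 6 - n_loss))
    gA <- mk_genes("c1", six, step = 1e5, ids = paste0("a", 1:6))
    gB <- mk_genes("c2", six[keep], step = 1e5, ids = paste0("b", keep))
    g <- species_genome("s", rbind(gA, gB))
    cls <- lapply(detect_clusters(g, six), score_integrity,
                  canonical_order = six)
    ohno <- data.frame(gene_a = paste0("a", keep), gene_b = paste0("b", keep))
    p <- pair_ohnologous_clusters(cls, ohno)$pairs[[1]]
    p$cluster_a$chromosome_id == "c1"  # intact copy got the intact label
  })
  expect_gte(mean(hits), 0.95)
})
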