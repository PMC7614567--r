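tiny_repertoire <- function(seqs_a, seqs_b) {
  tibble::tibble(mutant_a = seqs_a, mutant_b = seqs_b)
}

wt_pair <- list("AAAA", "CCCC")

test_that("mutation events are extracted with correct coordinates", {
  rep <- tiny_repertoire(c("ADAA", "AAAW"), c("CCCC", "DCCC"))
  mut <- repertoire_mutations(rep, wt_pair)
  expect_identical(nrow(mut), 3L)
  expect_identical(mut$protein, c("A", "A", "B"))
  expect_identical(mut$position, c(2L, 4L, 1L))
  expect_identical(mut$wt_aa, c("A", "A", "C"))
  expect_identical(mut$mut_aa, c("D", "W", "D"))
})

test_that("amino acid usage enrichment matches hand counts", {
  sel <- tiny_repertoire(c("ADAA", "ADAA", "AWAA", "AAAD", "ADAA"),
                         rep("CCCC", 5))
  bg <- tiny_repertoire(c("ADAA", "AWAA", "AYAA", "AWAA"), rep("CCCC", 4))
  tab <- aa_usage_enrichment(sel, bg, wt_pair)
  expect_identical(nrow(tab), 20L)
  # hand counts: selected D 4/5, W 1/5; background D 1/4, W 2/4, Y 1/4
  expect_equal(tab$ratio[tab$aa == "D"], (4 / 5) / (1 / 4))
  expect_equal(tab$ratio[tab$aa == "W"], (1 / 5) / (2 / 4))
  expect_identical(tab$ratio[tab$aa == "Y"], 0)           # absent in selected
  expect_true(is.na(tab$ratio[tab$aa == "K"]))            # absent in both
  expect_false(tab$defined[tab$aa == "K"])
  # an amino acid used only in the selection is flagged infinite
  sel2 <- tiny_repertoire("AKAA", "CCCC")
  tab2 <- aa_usage_enrichment(sel2, bg, wt_pair)
  expect_identical(tab2$ratio[tab2$aa == "K"], Inf)
  # self-comparison identity: every defined ratio is 1
  self <- aa_usage_enrichment(bg, bg, wt_pair)
  expect_true(all(self$ratio[self$defined] == 1))
})

test_that("substitution enrichment is keyed by the wild-type residue", {
  sel <- tiny_repertoire(c("DAAA", "AAAA"), c("CCCD", "DCCC"))
  bg <- tiny_repertoire(c("DAAA", "WAAA"), c("CCCD", "CCCD"))
  tab <- substitution_enrichment(sel, bg, wt_pair)
  expect_identical(nrow(tab), 400L)
  a_to_d <- tab$ratio[tab$from_aa == "A" & tab$to_aa == "D"]
  c_to_d <- tab$ratio[tab$from_aa == "C" & tab$to_aa == "D"]
  expect_equal(a_to_d, (1 / 3) / (1 / 4))
  expect_equal(c_to_d, (2 / 3) / (2 / 4))
  self <- substitution_enrichment(bg, bg, wt_pair)
  expect_true(all(self$ratio[self$defined] == 1))
})

test_that("position enrichment builds the exact Fisher table", {
  # 5 events at positions of interest, 5 outside; 5 + 5 available positions
  sel <- tiny_repertoire(
    c("DAAA", "DAAA", "DAAA", "ADAA", "ADAA"),
    c("DCCC", "CDCC", "CCDC", "CCCD", "CDCC")
  )
  poi <- c(1, 2, 3, 4, 5)      # A positions + B position 1 (concatenated)
  all_pos <- 1:8
  out <- position_enrichment(sel, poi, all_pos, wt_pair)
  expect_identical(out$events_in, 6L)   # 5 A events + B pos 1 event
  expect_identical(out$events_out, 4L)
  ft <- stats::fisher.test(matrix(c(6, 4, 5, 3), 2, byrow = TRUE))
  expect_equal(out$p_value, ft$p.value)
  expect_equal(out$odds_ratio, unname(ft$estimate))

  # balanced table gives odds ratio 1 and p = 1 (checked via the raw test)
  bal <- stats::fisher.test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(bal$p.value, 1)
  # diagonal table p equals exhaustive hypergeometric enumeration
  diag_p <- stats::fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value
  enum_p <- sum(stats::dhyper(0:10, 10, 10, 10)[
    stats::dhyper(0:10, 10, 10, 10) <= stats::dhyper(10, 10, 10, 10) + 1e-12])
  expect_equal(diag_p, enum_p)

  expect_error(position_enrichment(sel, integer(0), all_pos, wt_pair),
               "empty position set")
  # no mutations inside the set: odds ratio 0
  out0 <- position_enrichment(tiny_repertoire("AAAA", "CCDC"),
                              poi, all_pos, wt_pair)
  expect_equal(out0$odds_ratio, 0)
})

test_that("one-hot PCA explains variance correctly and respects duplicates", {
  # variation along a single one-hot axis: two states at one position
  seqs <- c(rep("AAAA", 6), rep("ACAA", 4))
  emb <- pca_embed_cluster(seqs, n_components = 2)
  expect_gt(emb$explained_variance[1], 1 - 1e-9)
  expect_true(all(diff(emb$explained_variance) <= 1e-12))
  expect_lt(sum(emb$explained_variance), 1 + 1e-9)
  # duplicated sequences land on identical coordinates
  expect_equal(emb$coords$pc1[1], emb$coords$pc1[2])
  # total variance is conserved across all components
  full <- pca_embed_cluster(seqs, n_components = 1)
  expect_equal(sum(full$sdev^2), full$total_variance, tolerance = 1e-9)
  expect_error(pca_embed_cluster(seqs, n_components = 50), "rank")
  expect_error(pca_embed_cluster("AAAA"), "at least 2")
})

test_that("k-means recovers planted mutant families", {
  fam1 <- paste0("AAAA", c("WWWW", "WWWY", "WWYW", "WYWW", "YWWW"))
  fam2 <- paste0("DDDD", c("KKKK", "KKKR", "KKRK", "KRKK", "RKKK"))
  emb <- pca_embed_cluster(c(fam1, fam2), n_components = 2, k_clusters = 2,
                           seed = 5)
  cl <- as.integer(emb$coords$cluster)
  expect_identical(length(unique(cl[1:5])), 1L)
  expect_identical(length(unique(cl[6:10])), 1L)
  expect_false(cl[1] == cl[6])
})

test_that("mutation frequency profile matches hand-tabulated fractions", {
  rep <- tiny_repertoire(c("ADAA", "ADAA", "AWAA", "AAAD"),
                         c("DCCC", "DCCC", "DCCC", "DCCC"))
  prof <- mutation_frequency_profile(rep, wt_pair)
  gf <- function(p, pos, aa) {
    prof$frequency[prof$protein == p & prof$position == pos & prof$aa == aa]
  }
  expect_equal(gf("A", 2, "D"), 2 / 4)
  expect_equal(gf("A", 2, "W"), 1 / 4)
  expect_equal(gf("A", 4, "D"), 1 / 4)
  expect_equal(gf("B", 1, "D"), 1)       # mutated in every mutant, sums to 1
  expect_true(all(prof$frequency[prof$protein == "A" & prof$position == 1]
                  == 0))                 # never mutated
  # wild-type residues are excluded from the profile
  expect_identical(gf("A", 2, "A"), 0)
  agg <- sum(prof$frequency[prof$protein == "A" & prof$position == 2])
  expect_equal(agg, 3 / 4)
})

test_that("pairwise hamming distribution counts all unordered pairs", {
  same <- pairwise_hamming_distribution(rep("AAAA", 5))
  expect_identical(sum(same$count), 10L)
  expect_identical(same$count[same$distance == 0], 10L)

  seqs <- c("AAAA", "AAAC", "AACC", "ACCC", "CCCC")
  out <- pairwise_hamming_distribution(seqs)
  expect_identical(sum(out$count), 10L)
  d_loop <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    d_loop <- c(d_loop, sum(strsplit(seqs[i], "")[[1]] !=
                              strsplit(seqs[j], "")[[1]]))
  }
  expect_identical(as.integer(table(factor(d_loop, levels = 0:4))),
                   out$count)
  expect_setequal(attr(out, "distances"), d_loop)
  expect_error(pairwise_hamming_distribution("AAAA"), "at least 2")
})

test_that("interface calling applies a strict 6-Angstrom heavy-atom cutoff", {
  ca <- tibble::tibble(residue = 1L, x = 0, y = 0, z = 0)
  cb <- tibble::tibble(residue = 7L, x = 5.9, y = 0, z = 0)
  out <- interface_positions(ca, cb)
  expect_identical(out$residue, c(1L, 7L))
  cb6 <- tibble::tibble(residue = 7L, x = 6.0, y = 0, z = 0)
  expect_identical(nrow(interface_positions(ca, cb6)), 0L)

  # random toy complex against an all-pairs double loop
  set.seed(33)
  ca <- tibble::tibble(residue = rep(1:10, each = 3),
                       x = runif(30, 0, 20), y = runif(30, 0, 20),
                       z = runif(30, 0, 20))
  cb <- tibble::tibble(residue = rep(1:10, each = 3),
                       x = runif(30, 0, 20), y = runif(30, 0, 20),
                       z = runif(30, 0, 20))
  out <- interface_positions(ca, cb)
  hit_a <- hit_b <- integer(0)
  for (i in seq_len(30)) for (j in seq_len(30)) {
    d <- sqrt((ca$x[i] - cb$x[j])^2 + (ca$y[i] - cb$y[j])^2 +
                (ca$z[i] - cb$z[j])^2)
    if (d < 6) {
      hit_a <- c(hit_a, ca$residue[i])
      hit_b <- c(hit_b, cb$residue[j])
    }
  }
  expect_identical(out$residue[out$protein == "A"], sort(unique(hit_a)))
  expect_identical(out$residue[out$protein == "B"], sort(unique(hit_b)))
  expect_error(interface_positions(ca[0, ], cb), "malformed")
})

test_that("PDB reading extracts heavy atoms per chain", {
  skip_if_not_installed("bio3d")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  H   ALA A   1       2.000   1.000   0.000  1.00  0.00           H",
    "ATOM      4  N   GLY B   1       4.000   0.000   0.000  1.00  0.00           N",
    "ATOM      5  CA  GLY B   1       5.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  coords <- read_structure_pair(f, chain_a = "A", chain_b = "B")
  expect_identical(nrow(coords$a), 2L)   # hydrogen excluded
  expect_identical(nrow(coords$b), 2L)
  out <- interface_positions(coords$a, coords$b)
  expect_identical(nrow(out), 2L)        # 2.5 A closest approach
})
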