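test_that("domain exclusion removes Archaea and Eukarya but keeps unknowns", {
  ct <- toy_counts(matrix(1:9, 3, 3),
                   domains = c("Bacteria", "Archaea", "Eukarya"))
  out <- suppressMessages(exclude_domains(ct))
  expect_equal(rownames(out$counts), "t1")

  all_bact <- toy_counts(matrix(1:9, 3, 3))
  expect_identical(exclude_domains(all_bact)$counts, all_bact$counts)
  expect_identical(exclude_domains(ct, character(0))$counts, ct$counts)

  # unparseable domain rank: retained, logged
  ct2 <- count_table(matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
                     lineage = c("", "Archaea;x"))
  expect_message(out2 <- exclude_domains(ct2), "unparseable")
  expect_equal(rownames(out2$counts), "a")
})

test_that("genus aggregation sums counts and preserves sample depths", {
  mat <- matrix(c(3, 4, 10, 1, 2, 5), 3, 2,
                dimnames = list(c("otu1", "otu2", "otu3"), c("s1", "s2")))
  ct <- count_table(mat, lineage = c("Bacteria;Firmicutes;c;o;f;Streptococcus",
                                     "Bacteria;Firmicutes;c;o;f;Streptococcus",
                                     "Bacteria;Firmicutes;c;o;f;Gemella"))
  ag <- aggregate_genus(ct)
  expect_equal(unname(ag$counts["Streptococcus", ]), c(7, 3))
  expect_equal(nrow(ag$counts), 2)
  # depths conserved on a random table with random genus assignments,
  # empty genus pooled into "unclassified"
  set.seed(3)
  rmat <- matrix(rpois(120, 8), 12, 10)
  genera <- rep_len(c("g1", "g2", "g3", ""), 12)
  rct <- toy_counts(rmat, lineage = paste0("Bacteria;", genera))
  rag <- aggregate_genus(rct)
  expect_equal(colSums(rag$counts), colSums(rct$counts))
  expect_true("unclassified" %in% rownames(rag$counts))
  expect_equal(unname(rag$counts["unclassified", ]),
               unname(colSums(rmat[genera == "", , drop = FALSE])))
  # all-distinct genera: row count unchanged
  dct <- toy_counts(rmat)
  expect_equal(nrow(aggregate_genus(dct)$counts), nrow(rmat))
})

test_that("sample depth filter uses an inclusive >= 1000 boundary", {
  mat <- cbind(s999 = c(500, 499), s1000 = c(500, 500), s1500 = c(1000, 500))
  rownames(mat) <- c("a", "b")
  ct <- count_table(mat)
  out <- suppressMessages(filter_sample_depth(ct))
  expect_equal(colnames(out$counts), c("s1000", "s1500"))
  # already-deep table unchanged
  deep <- count_table(cbind(s1 = c(1000, 500), s2 = c(1500, 500)) |>
                        (\(m) {rownames(m) <- c("a", "b"); m})())
  expect_identical(filter_sample_depth(deep)$counts, deep$counts)
  expect_error(filter_sample_depth(ct, min_reads = 1e7), "all samples")
})

test_that("prevalence filter keeps taxa with > 3 counts in >= 5% of samples", {
  n_samp <- 20
  mat <- rbind(boundary = c(4, rep(0, n_samp - 1)),        # 1/20 = 5% -> kept
               allthrees = rep(3, n_samp),                 # never > 3 -> dropped
               common = rep(c(100, 0), each = n_samp / 2)) # kept
  colnames(mat) <- paste0("s", seq_len(n_samp))
  ct <- count_table(mat)
  out <- suppressMessages(prevalence_filter(ct))
  expect_setequal(rownames(out$counts), c("boundary", "common"))
  expect_error(prevalence_filter(count_table(mat["allthrees", , drop = FALSE])),
               "every taxon")
})

test_that("single-sample patients are excluded", {
  meta <- validate_metadata(toy_meta(paste0("s", 1:8),
                                     cluster = rep(c("A", "B", "C"), c(1, 2, 5))))
  out <- suppressMessages(drop_singleton_clusters(meta))
  expect_setequal(unique(out$cluster_id), c("B", "C"))
  meta2 <- validate_metadata(toy_meta(paste0("s", 1:4), cluster = c("A", "A", "B", "B")))
  expect_identical(drop_singleton_clusters(meta2), meta2)
  meta3 <- validate_metadata(toy_meta(paste0("s", 1:2), cluster = c("A", "B")))
  expect_error(drop_singleton_clusters(meta3), "single sample")
})

test_that("log-proportion transform matches hand-computed values", {
  ct <- count_table(matrix(c(5, 4, 1), 3, 1,
                           dimnames = list(c("a", "b", "c"), "s1")))
  M <- lognorm_transform(ct)
  expect_equal(unname(M["s1", "c"]), log10(1.5 / 10), tolerance = 1e-12)
  expect_equal(unname(M["s1", "c"]), -0.823909, tolerance = 1e-6)

  ct0 <- count_table(matrix(c(0, 10), 2, 1, dimnames = list(c("a", "b"), "s1")))
  expect_equal(unname(lognorm_transform(ct0)["s1", "a"]), -1.301030,
               tolerance = 1e-6)

  ct1 <- count_table(matrix(2, 1, 1, dimnames = list("a", "s1")))
  expect_equal(unname(lognorm_transform(ct1)["s1", "a"]), 0.096910,
               tolerance = 1e-6)  # pseudo-count can push values above 0

  ctz <- count_table(matrix(c(0, 0, 1, 1), 2, 2,
                            dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_error(lognorm_transform(ctz), "zero-depth")

  # alternative placement: 0.5 added to the proportion
  Mp <- lognorm_transform(ct0, pseudo = "proportion")
  expect_equal(unname(Mp["s1", "a"]), log10(0.5), tolerance = 1e-12)
})

test_that("transform conserves mass and converges to log10 proportions", {
  set.seed(11)
  mat <- matrix(rpois(60, 30), 6, 10)
  ct <- toy_counts(mat)
  M <- lognorm_transform(ct)
  depth <- colSums(mat)
  # sum_t 10^Mlog = 1 + 0.5 * H / D exactly, per sample
  expect_equal(unname(rowSums(10^M)), unname(1 + 0.5 * nrow(mat) / depth),
               tolerance = 1e-12)
  # depth -> infinity at fixed proportions
  base <- c(5, 3, 2)
  errs <- sapply(c(1, 100, 10000), function(f) {
    cc <- count_table(matrix(base * f, 3, 1,
                             dimnames = list(letters[1:3], "s")))
    max(abs(lognorm_transform(cc)[1, ] - log10(base / sum(base))))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("alpha diversity indices match their closed forms", {
  ct <- count_table(matrix(c(3, 0, 1, 0), 4, 1,
                           dimnames = list(paste0("g", 1:4), "s1")))
  expect_equal(unname(alpha_diversity(ct, "observed")), 2)

  unif <- count_table(matrix(rep(25, 4), 4, 1,
                             dimnames = list(paste0("g", 1:4), "s1")))
  expect_equal(unname(alpha_diversity(unif, "shannon")), log(4),
               tolerance = 1e-12)
  expect_equal(unname(alpha_diversity(unif, "simpson")), 0.75,
               tolerance = 1e-12)
  expect_equal(unname(alpha_diversity(unif, "simpson", inverse_simpson = TRUE)),
               4, tolerance = 1e-12)

  # hand-formula cross-check on random data, plus range invariants
  set.seed(5)
  mat <- matrix(rpois(50, 4), 5, 10)
  mat[, 1] <- c(10, 0, 0, 0, 0)
  ct2 <- toy_counts(mat)
  p <- sweep(mat, 2, colSums(mat), "/")
  sh_hand <- apply(p, 2, function(q) {q <- q[q > 0]; -sum(q * log(q))})
  expect_equal(unname(alpha_diversity(ct2, "shannon")), unname(sh_hand),
               tolerance = 1e-10)
  expect_true(all(alpha_diversity(ct2, "shannon") >= 0))
  si <- alpha_diversity(ct2, "simpson")
  expect_true(all(si >= 0 & si < 1))
  expect_true(all(alpha_diversity(ct2, "observed") <= nrow(mat)))
  ctz <- count_table(matrix(c(0, 1), 2, 1, dimnames = list(c("a", "b"), "s")))
  ctz$counts[, 1] <- 0
  expect_error(alpha_diversity(ctz, "shannon"), "zero-depth")
})

test_that("the preprocessing chain is idempotent and fully reported", {
  d <- simulate_mediation_data(n = 12, m_range = c(2, 4), H = 15, s = 2,
                               depth_range = c(1200, 3000), seed = 21)
  # inject an archaeal taxon, a rare taxon, and a shallow sample
  counts <- d$counts$counts
  lineage <- d$counts$lineage
  counts <- rbind(counts, Arch1 = rpois(ncol(counts), 50),
                  Rare1 = c(4, rep(0, ncol(counts) - 1)) * 0)
  lineage <- c(lineage, Arch1 = "Archaea;Arch1", Rare1 = "Bacteria;Rare1")
  counts[, 3] <- round(counts[, 3] * 500 / sum(counts[, 3]))  # depth < 1000
  ct <- count_table(counts, lineage)
  meta <- validate_metadata(d$metadata)

  pp <- suppressMessages(preprocess_counts(ct, meta))
  expect_false("Arch1" %in% rownames(pp$counts$counts))
  expect_false("Rare1" %in% rownames(pp$counts$counts))
  expect_true(all(colSums(pp$counts$counts) >= 1000))
  expect_true(all(table(pp$metadata$cluster_id) >= 2))
  # report is monotone non-increasing and consistent
  rep1 <- pp$report
  expect_true(all(rep1$n_taxa_out <= rep1$n_taxa_in))
  expect_true(all(rep1$n_samples_out <= rep1$n_samples_in))

  pp2 <- suppressMessages(preprocess_counts(pp$counts, pp$metadata))
  expect_identical(pp2$counts$counts, pp$counts$counts)
  expect_identical(pp2$metadata$sample_id, pp$metadata$sample_id)
})
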