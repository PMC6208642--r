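test_that("log transform applies once with the documented offset", {
  em <- expression_matrix(matrix(c(0, 1, 100), 1, dimnames = list("g", NULL)))
  lt <- log_transform(em)
  expect_equal(unname(lt$tpm[1, 1]), log2(1e-5), tolerance = 1e-12)
  expect_equal(unname(lt$tpm[1, 2]), log2(1 + 1e-5), tolerance = 1e-12)
  expect_equal(lt$transform, "log2")
  expect_error(log_transform(lt), "already transformed")
  expect_error(expression_matrix(matrix(-1, 1)), ">= 0")

  ## monotone: per-gene sample ranks preserved
  m <- matrix(rexp(30), 3, 10)
  l2 <- log_transform(expression_matrix(m))$tpm
  for (g in 1:3) expect_equal(rank(l2[g, ]), rank(m[g, ]))
})

test_that("taxa-gene screen recovers planted links and is rank-invariant", {
  com <- generate_community(community_config(n_samples = 60, seed = 3))
  links <- data.frame(gene = c(5, 9), taxon = c(1, 3), slope = 1.0, noise_sd = 0.5)
  expr <- generate_expression(com$table, com$labels,
                              expression_config(n_genes = 30,
                                                taxon_linked_genes = links,
                                                seed = 4))
  rel <- to_relative(com$table)
  em <- log_transform(expression_matrix(expr))
  out <- taxa_gene_screen(rel, em)
  expect_true(any(out$pairs$taxon == "taxon_1" & out$pairs$gene == "gene_5"))
  expect_true(any(out$pairs$taxon == "taxon_3" & out$pairs$gene == "gene_9"))
  expect_true(all(out$pairs$p < 0.01 & out$pairs$q < 0.01))

  ## Spearman invariance: raw TPM and log TPM give identical screens
  out_raw <- taxa_gene_screen(rel, expression_matrix(expr))
  expect_equal(out$pairs$rho, out_raw$pairs$rho, tolerance = 1e-12)
  expect_equal(out$pairs$p, out_raw$pairs$p, tolerance = 1e-12)

  ## noiseless link: recovered with |rho| = 1
  expr0 <- generate_expression(com$table, com$labels,
    expression_config(n_genes = 10,
                      taxon_linked_genes = data.frame(gene = 1, taxon = 2,
                                                      slope = 1, noise_sd = 0),
                      seed = 5))
  out0 <- taxa_gene_screen(rel, expression_matrix(expr0))
  hit <- out0$pairs[out0$pairs$gene == "gene_1" & out0$pairs$taxon == "taxon_2", ]
  expect_equal(hit$rho, 1)
})

test_that("taxa-gene screen makes near-zero discoveries on independent data", {
  com <- generate_community(community_config(n_samples = 30, seed = 6))
  rel <- to_relative(com$table)
  expr <- generate_expression(com$table, com$labels,
                              expression_config(n_genes = 50, seed = 7))
  out <- taxa_gene_screen(rel, expression_matrix(expr))
  expect_lte(nrow(out$pairs), 1)
})

test_that("subgroup DE screen recovers planted shifts and controls the null", {
  labels <- rep(1:2, each = 20)
  com <- generate_community(community_config(n_samples = 40, K = 2,
                                             mixing = c(0.5, 0.5), seed = 8))
  shift <- data.frame(gene = 1:50, component = 1, log2_effect = 2)
  expr <- generate_expression(com$table, labels,
                              expression_config(n_genes = 200,
                                                subgroup_shift_genes = shift,
                                                seed = 9))
  em <- log_transform(expression_matrix(expr))
  de <- subgroup_de_screen(em, labels)
  planted <- paste0("gene_", 1:50)
  expect_gte(sum(planted %in% de$significant), 45)

  ## permuted labels: essentially nothing survives padj < 0.01
  set.seed(10)
  de_null <- subgroup_de_screen(em, sample(labels))
  expect_lte(length(de_null$significant), 2)

  ## constant genes are skipped, never reported
  const <- em
  const$tpm[1, ] <- 5
  de_c <- subgroup_de_screen(const, labels)
  expect_false("gene_1" %in% de_c$significant)
  expect_true(is.na(de_c$table$p[de_c$table$gene == "gene_1"]))

  expect_warning(subgroup_de_screen(em, c(rep(1, 19), rep(2, 19), 3, 3)),
                 "excluding")
})

test_that("gene-set comparison counts significant genes and direction", {
  set.seed(11)
  labels <- rep(1:2, each = 12)
  base <- matrix(2^rnorm(13 * 24, 4), 13, 24,
                 dimnames = list(paste0("G", 1:13), NULL))
  gs <- gene_set("toy", c(paste0("G", 1:13), "MISSING1"))

  same <- geneset_compare(expression_matrix(base), labels, gs, c(1, 2))
  expect_lte(same$n_significant, 2)  # null: few spurious hits at 0.05
  expect_equal(same$missing, "MISSING1")

  up <- base; up[, labels == 1] <- up[, labels == 1] * 8
  shifted <- geneset_compare(expression_matrix(up), labels, gs, c(1, 2))
  expect_equal(shifted$direction_consistency, 1)
  expect_gte(shifted$n_significant, 10)

  ## tiny subgroup: exact MWU floor respected, no crash
  tiny <- geneset_compare(expression_matrix(base), c(1, rep(2, 23)), gs, c(1, 2))
  expect_true(all(tiny$table$p >= 2 / 24))
})

test_that("cytokine comparison flags planted shifts, stable under reordering", {
  set.seed(12)
  labels <- rep(1:3, each = 15)
  cyt <- matrix(rexp(5 * 45, 1), 5, 45,
                dimnames = list(c("IL6", "IL8", "IL1A", "TNF", "IL10"), NULL))
  cyt["IL6", labels == 1] <- cyt["IL6", labels == 1] * 3
  out <- cytokine_compare(cyt, labels)
  expect_true("IL6" %in% out$significant)
  out2 <- cytokine_compare(cyt[sample(5), ], labels)
  expect_identical(out$table, out2$table)
  expect_error(cytokine_compare(matrix("a", 1, 3), rep(1, 3)), "non-numeric")

  flat <- matrix(1, 2, 45, dimnames = list(c("A", "B"), NULL))
  expect_length(cytokine_compare(flat, labels)$significant, 0)
})

test_that("the bundled Th17 gene set loads and is overridable", {
  gs <- th17_geneset()
  expect_s3_class(gs, "gene_set")
  expect_length(gs$genes, 13)
  expect_true(all(c("IL6", "TGFB1", "STAT3", "RORC", "IL17A") %in% gs$genes))

  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A", "B"), path)
  expect_equal(th17_geneset(path)$genes, c("A", "B"))
})
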