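test_that("one-sided conversion follows the sign of the effect", {
  expect_equal(one_sided(0.1, 1, "activation"), 0.05)
  expect_equal(one_sided(0.1, 1, "inhibition"), 0.95)
  expect_equal(one_sided(0.1, -1, "activation"), 0.95)
  expect_equal(one_sided(0.1, -1, "inhibition"), 0.05)
  expect_equal(one_sided(1, 1, "activation"), 0.5)
  expect_equal(one_sided(1, -1, "inhibition"), 0.5)
  expect_equal(one_sided(0.3, 0, "activation"), 0.5)
  expect_error(one_sided(0, 1, "activation"), "0, 1")
})

test_that("Brown's method reduces to Fisher under independence", {
  # k = 2, p = (0.5, 0.5): X2 = -4 log 0.5, f = 4
  b <- brown_combine(c(0.5, 0.5), diag(2))
  expect_equal(b$x2, -4 * log(0.5), tolerance = 1e-12)
  expect_equal(b$c, 1)
  expect_equal(b$f, 4)
  fisher <- stats::pchisq(-4 * log(0.5), df = 4, lower.tail = FALSE)
  expect_equal(b$p_combined, fisher, tolerance = 1e-12)
  expect_equal(round(b$x2, 4), 2.7726)
  expect_equal(round(b$p_combined, 4), 0.5966)

  # general grid, k up to 6
  set.seed(8)
  for (k in c(2, 4, 6)) {
    p <- stats::runif(k, 0.01, 0.99)
    b <- brown_combine(p, diag(k))
    expect_equal(b$f, 2 * k)
    expect_equal(b$p_combined,
                 stats::pchisq(-2 * sum(log(p)), 2 * k, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("Brown with a single p or perfectly duplicated genes returns that p", {
  expect_equal(brown_combine(0.123)$p_combined, 0.123, tolerance = 1e-12)
  expect_equal(brown_combine(0.123)$c, 1)
  expect_equal(brown_combine(0.123)$f, 2)
  # duplicated gene (corr 1, identical p twice): Kost polynomial gives
  # cov = 4 exactly at rho = 1, making the combination collapse to p
  for (p in c(0.01, 0.1, 0.3, 0.5, 0.9)) {
    b <- brown_combine(c(p, p), matrix(1, 2, 2))
    expect_equal(b$p_combined, p, tolerance = 0.02 * p + 1e-6)
  }
})

test_that("pathway PVAL and global adjustment follow their formulas", {
  expect_equal(pathway_pval(0.01, 0.8), 0.02)
  expect_equal(pathway_pval(0.5, 0.5), 1)
  expect_equal(pathway_pval(1, 1), 1)
  # swap invariance
  set.seed(14)
  a <- stats::runif(50, 1e-6, 1); b <- stats::runif(50, 1e-6, 1)
  expect_equal(pathway_pval(a, b), pathway_pval(b, a))
  expect_equal(pathway_pval(a, b), pmin(1, 2 * pmin(a, b)))

  expect_equal(adjust_global(0.001, K = 225), 0.225)
  expect_equal(adjust_global(0.2, K = 10), 1)
  expect_equal(adjust_global(0.37, K = 1), 0.37)
  p <- stats::runif(20)
  expect_equal(adjust_global(p, K = 20), pmin(20 * p, 1))
})

test_that("DEG selection matches hand-computed BH and Bonferroni", {
  fits <- data.frame(gene = c("a", "b", "c"),
                     p_two_sided = c(0.001, 0.5, 0.9))
  # BH: sorted p * m / rank = (0.003, 0.75, 0.9), cummin from the right
  expect_equal(select_degs(fits, "BH", 0.05), "a")
  fits2 <- data.frame(gene = c("a", "b", "c"),
                      p_two_sided = c(0.01, 0.02, 0.04))
  # Bonferroni: (0.03, 0.06, 0.12) -> one DEG at 0.05
  expect_equal(select_degs(fits2, "bonferroni", 0.05), "a")
  fits3 <- data.frame(gene = c("a", "b"), p_two_sided = c(1, 1))
  expect_length(select_degs(fits3, "BH", 0.05), 0)
  expect_error(select_degs(fits, "fdr-ish", 0.05), "BH")
})

test_that("perturbation labels cover the four cells and the NA case", {
  up <- list(status = "up", weight_sum = 2L)
  dn <- list(status = "down", weight_sum = -1L)
  na <- list(status = "not_available", weight_sum = 0L)
  expect_equal(perturbation_status(up, 0.001, 0.9), "up act")
  expect_equal(perturbation_status(up, 0.9, 0.001), "down act")
  expect_equal(perturbation_status(dn, 0.001, 0.9), "down inh")
  expect_equal(perturbation_status(dn, 0.9, 0.001), "up inh")
  expect_equal(perturbation_status(na, 0.001, 0.9), "NA")
  expect_warning(out <- perturbation_status(up, 0.5, 0.5), "tie")
  expect_equal(out, "up act")
})

test_that("pathway ranks are dense with percentile over unique values", {
  r <- rank_pathways(c(0.001, 0.5, 0.5))
  expect_equal(r$rank, c(1, 2, 2))
  expect_equal(r$percentile, c(50, 100, 100))

  r2 <- rank_pathways(c(0.4, 0.1, 0.2, 0.3))
  expect_equal(r2$percentile[which.min(c(0.4, 0.1, 0.2, 0.3))], 100 / 4)

  r3 <- rank_pathways(rep(0.2, 5))
  expect_equal(r3$percentile, rep(100, 5))
})

test_that("semgsa recovers a planted shift and orders its table by PVAL", {
  set.seed(19)
  gs <- simulate_pathways(4, c(12, 18), seed = 5)
  genes <- sort(unique(unlist(lapply(gs, function(g) g$nodes))))
  hits <- 0
  for (s in 1:5) {
    data <- generate_base_data(genes, 25, 25, corr = "independent")
    aff <- data.frame(gene = gs[[1]]$nodes, sign = 1L)
    data <- inject_signal(data, aff, 0.7)
    fit <- quiet_semgsa(gs, data, n_rep = 300)
    expect_equal(fit$gsa$PVAL, sort(fit$gsa$PVAL))
    expect_equal(fit$gsa$ADJP, pmin(4 * fit$gsa$PVAL, 1))
    row <- fit$gsa[fit$gsa$pathway == gs[[1]]$name, ]
    if (row$PVAL < 0.05 && row$pNA < row$pNI) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("semgsa handles missing genes, tiny pathways and K = 1", {
  set.seed(23)
  g <- chain_graph(c("A", "B", "C"))
  data <- noise_data(c("A", "B"), 10, 10)  # C absent -> dropped
  expect_message(fit <- suppressWarnings(semgsa(g, data, n_rep = 100)),
                 "dropped 1")
  expect_equal(fit$gsa$No.nodes, 2)
  expect_equal(fit$gsa$ADJP, fit$gsa$PVAL)  # K = 1

  tiny <- pathway_graph("tiny", nodes = c("A", "Z9"))
  expect_warning(
    fit2 <- suppressMessages(semgsa(list(g, tiny), data, n_rep = 100)),
    "fewer than 2")
  expect_equal(nrow(fit2$gsa), 1)
  # ADJP still uses K = number of input pathways
  expect_equal(fit2$gsa$ADJP, pmin(2 * fit2$gsa$PVAL, 1))
})

test_that("semgsa output is reproducible under a fixed seed", {
  set.seed(33)
  gs <- simulate_pathways(3, c(8, 12), seed = 2)
  genes <- sort(unique(unlist(lapply(gs, function(g) g$nodes))))
  data <- noise_data(genes, 12, 12)
  f1 <- quiet_semgsa(gs, data, n_rep = 150, seed = 99)
  f2 <- quiet_semgsa(gs, data, n_rep = 150, seed = 99)
  expect_identical(f1$gsa, f2$gsa)
  expect_identical(f1$DEG, f2$DEG)
})

test_that("stricter alpha never adds DEGs", {
  set.seed(44)
  gs <- simulate_pathways(2, c(10, 14), seed = 3)
  genes <- sort(unique(unlist(lapply(gs, function(g) g$nodes))))
  data <- generate_base_data(genes, 20, 20, corr = "independent")
  data <- inject_signal(data,
                        data.frame(gene = gs[[1]]$nodes[1:5], sign = 1L),
                        1)
  strict <- quiet_semgsa(gs, data, alpha = 0.01, n_rep = 200, seed = 1)
  loose <- quiet_semgsa(gs, data, alpha = 0.10, n_rep = 200, seed = 1)
  for (nm in names(strict$DEG))
    expect_true(all(strict$DEG[[nm]] %in% loose$DEG[[nm]]))
})

test_that("semgsa methods print, summarise and expose coefficients", {
  set.seed(50)
  g <- chain_graph()
  data <- noise_data(c("A", "B", "C"), 10, 10)
  fit <- quiet_semgsa(g, data, n_rep = 100, seed = 1)
  expect_output(print(fit), "Top pathways")
  expect_output(print(summary(fit)), "Pathways analysed")
  cf <- coef(fit)
  expect_named(cf, "chain")
  expect_named(cf$chain, c("A", "B", "C"))
})
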