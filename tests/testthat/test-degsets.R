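# Build a pair of deg_calls over a shared universe with prescribed common /
# unique component sizes and |log2fc| values for the unique components.
build_call_pair <- function(n_common, n_uq, n_deseq, lfc_uq = 2, lfc_deseq = 2.5,
                            fdr = 0.05) {
  n_extra <- 50
  ids <- sprintf("gene%05d", seq_len(n_common + n_uq + n_deseq + n_extra))
  common <- ids[seq_len(n_common)]
  uq_only <- ids[n_common + seq_len(n_uq)]
  deseq_only <- ids[n_common + n_uq + seq_len(n_deseq)]

  mk_result <- function(called, lfc_called) {
    lfc <- rep(0.1, length(ids))
    padj <- rep(0.9, length(ids))
    lfc[match(called, ids)] <- lfc_called
    padj[match(called, ids)] <- 0.01
    new_test_result(log2fc = lfc, padj = padj, gene_id = ids)
  }
  res_uq <- mk_result(c(common, uq_only),
                      c(rep(3, length(common)), rep(lfc_uq, length(uq_only))))
  res_deseq <- mk_result(c(common, deseq_only),
                         c(rep(3, length(common)),
                           rep(lfc_deseq, length(deseq_only))))
  list(uq = call_degs(res_uq, fdr = fdr, lfc_cutoff = 1),
       deseq = call_degs(res_deseq, fdr = fdr, lfc_cutoff = 1))
}

test_that("the combining rule reproduces both worked set-size examples", {
  p <- build_call_pair(1546, 38, 109, lfc_uq = 2, lfc_deseq = 2.5)
  comb <- combine_true_degs(p$uq, p$deseq, max_cutoff_uq = 2,
                            max_cutoff_deseq = 2.5)
  expect_equal(nrow(comb), 1693L)
  expect_equal(attr(comb, "n_common"), 1546L)
  expect_equal(attr(comb, "n_uq_only"), 38L)
  expect_equal(attr(comb, "n_deseq_only"), 109L)

  p2 <- build_call_pair(2212, 3, 84, lfc_uq = 2, lfc_deseq = 2)
  comb2 <- combine_true_degs(p2$uq, p2$deseq, max_cutoff_uq = 2,
                             max_cutoff_deseq = 2)
  expect_equal(nrow(comb2), 2299L)
})

test_that("combined sets obey the provenance partition and cutoff invariants", {
  p <- build_call_pair(20, 10, 15, lfc_uq = 2.2, lfc_deseq = 2.6)
  comb <- combine_true_degs(p$uq, p$deseq, max_cutoff_uq = 2,
                            max_cutoff_deseq = 2.5)
  # classes disjoint and summing to the total
  expect_false(anyDuplicated(comb$gene_id) > 0)
  expect_equal(nrow(comb),
               attr(comb, "n_common") + attr(comb, "n_uq_only") +
                 attr(comb, "n_deseq_only"))
  # unique genes exceed the max cutoffs in their own route
  expect_true(all(abs(comb$log2fc_uq[comb$provenance == "uq_only"]) >= 2))
  expect_true(all(abs(comb$log2fc_deseq[comb$provenance == "deseq_only"]) >= 2.5))
  # superset of the intersection, subset of the union of the call sets
  expect_true(all(intersect(p$uq$gene_id, p$deseq$gene_id) %in% comb$gene_id))
  expect_true(all(comb$gene_id %in% union(p$uq$gene_id, p$deseq$gene_id)))

  # method-unique genes below the max cutoff are excluded entirely
  p0 <- build_call_pair(0, 5, 5, lfc_uq = 1.2, lfc_deseq = 1.2)
  comb0 <- combine_true_degs(p0$uq, p0$deseq, max_cutoff_uq = 2,
                             max_cutoff_deseq = 2.5)
  expect_equal(nrow(comb0), 0L)
})

test_that("mismatched FDR or gene universes are rejected", {
  p <- build_call_pair(5, 2, 2)
  other <- call_degs(new_test_result(log2fc = c(3, 3),
                                     padj = c(0.01, 0.01)),
                     fdr = 0.05, lfc_cutoff = 1)
  expect_error(combine_true_degs(p$uq, other, 2, 2), "universes")
  p_fdr <- build_call_pair(5, 2, 2, fdr = 0.1)
  expect_error(combine_true_degs(p$uq, p_fdr$deseq, 2, 2), "FDR")
})

test_that("subtype comparison partitions the union and matches the worked overlap", {
  cmp <- compare_subtype_sets(c("a", "b", "c"), c("b", "c", "d"))
  expect_setequal(cmp$common, c("b", "c"))
  expect_equal(cmp$unique_a, "a")
  expect_equal(cmp$unique_b, "d")

  # symmetric up to swapping the unique labels
  cmp_rev <- compare_subtype_sets(c("b", "c", "d"), c("a", "b", "c"))
  expect_setequal(cmp_rev$common, cmp$common)
  expect_equal(cmp_rev$unique_a, cmp$unique_b)
  expect_equal(cmp_rev$unique_b, cmp$unique_a)

  # identical sets leave no unique genes
  same <- compare_subtype_sets(c("x", "y"), c("x", "y"))
  expect_length(same$unique_a, 0)
  expect_length(same$unique_b, 0)

  # cardinality arithmetic at the published sizes: |A|=1693, |B|=2299,
  # overlap 896 forces 797 and 1403 unique genes
  a <- sprintf("s%04d", 1:1693)
  b <- c(a[1:896], sprintf("t%04d", 1:1403))
  cmp2 <- compare_subtype_sets(a, b)
  expect_length(cmp2$common, 896)
  expect_length(cmp2$unique_a, 797)
  expect_length(cmp2$unique_b, 1403)
  expect_equal(sum(cmp2$summary$n), length(union(a, b)))
})

test_that("direction summaries count signs and reject zero fold changes", {
  s <- tibble::tibble(gene_id = c("a", "b", "c"), log2fc = c(2.1, -3, 4))
  expect_equal(summarize_direction(s),
               tibble::tibble(n_up = 2L, n_down = 1L, n_total = 3L))
  empty <- tibble::tibble(gene_id = character(), log2fc = numeric())
  expect_equal(summarize_direction(empty)$n_total, 0L)
  bad <- tibble::tibble(gene_id = "z", log2fc = 0)
  expect_error(summarize_direction(bad), "log2fc == 0")

  # conservation on a real call set
  res <- new_test_result(log2fc = c(2, -2, 3, 1.5, -0.2),
                         padj = c(0.01, 0.01, 0.01, 0.01, 0.01))
  call <- call_degs(res, lfc_cutoff = 1.5)
  sd <- summarize_direction(call)
  expect_equal(sd$n_up + sd$n_down, nrow(call))
})

test_that("biomarker lookup reports both routes and flags absent genes", {
  res_uq <- new_test_result(log2fc = c(-2.5, 1), padj = c(0.001, 0.4),
                            gene_id = c("PGR", "OTHER"))
  res_deseq <- new_test_result(log2fc = c(-2.8, 0.9), padj = c(0.002, 0.5),
                               gene_id = c("PGR", "OTHER"))
  rep <- biomarker_report(res_uq, res_deseq, c("ESR1", "PGR"))
  expect_equal(nrow(rep), 4L)
  expect_true(all(rep$absent[rep$gene_id == "ESR1"]))
  expect_false(any(rep$absent[rep$gene_id == "PGR"]))
  expect_true(all(rep$log2fc[rep$gene_id == "PGR"] < 0))
  expect_equal(nrow(biomarker_report(res_uq, res_deseq, character())), 0L)
})

test_that("a spiked down-regulated gene is negative in both routes end to end", {
  sim <- simulate_counts(n_genes = 800, n1 = 8, n2 = 8, dispersion = 0.1,
                         skew_fraction = 0, de_fraction = 0.05,
                         lfc_magnitudes = 3, de_up_fraction = 0, seed = 19)
  x <- suppressMessages(filter_all_zero_genes(sim$counts))
  res_uq <- deg_test(x, sim$samples, "g2", "g1", route = "uq-pgq2")
  res_mor <- deg_test(x, sim$samples, "g2", "g1", route = "deseq-mor")
  down <- sim$truth$gene_id[sim$truth$true_log2fc < 0]
  down <- intersect(down, res_uq$gene_id)
  rep <- biomarker_report(res_uq, res_mor, down)
  expect_true(all(rep$log2fc < 0))
})
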