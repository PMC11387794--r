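test_that("signature union cardinality follows |A| + |B| - |A ∩ B|", {
  # 5 cancer + 4 CAF genes sharing exactly one -> 8-gene signature
  sig8 <- signature_definition("sig8", c("A", "B", "C", "D", "E"),
                               c("E", "F", "G", "H"))
  expect_length(sig8$genes, 8L)

  # 2 + 29 sharing one -> 30-gene signature
  sig30 <- signature_definition("sig30", c("X1", "S"),
                                c("S", sprintf("Y%02d", 1:28)))
  expect_length(sig30$genes, 30L)

  # property on random lists
  set.seed(8)
  for (i in 1:20) {
    a <- sample(LETTERS, sample(3:10, 1))
    b <- sample(LETTERS, sample(3:10, 1))
    s <- signature_definition("s", a, b)
    expect_length(s$genes, length(a) + length(b) - length(intersect(a, b)))
  }
})

test_that("pathway-frequency selection keeps genes at the inclusive 20% boundary", {
  # one dataset, 10 enriched sets; gene 'edge' belongs to exactly 2 of them
  genes <- sprintf("g%02d", 1:40)
  sets <- lapply(1:10, function(i) c(sprintf("g%02d", ((2 * i) %% 30) + 1:5), "core"))
  names(sets) <- sprintf("S%02d", 1:10)
  sets$S01 <- c(sets$S01, "edge")
  sets$S02 <- c(sets$S02, "edge")
  res <- data.frame(set = names(sets), size = lengths(sets),
                    es = 0.8, nes = 2, p_perm = 0.001, fdr_q = 0.001,
                    n_perm = 1000L, stringsAsFactors = FALSE)
  res$leading_edge <- unname(sets)  # every member in the leading edge
  enr <- list(list(dataset_id = "d1", cell_type = "cancer", result = res))
  sig <- suppressWarnings(
    derive_frequency_signature(enr, sets, derivation_params()))
  # edge: 2 of 10 sets = 20% -> kept (ceiling(0.2 * 10) = 2); core: 10/10 kept
  expect_true("edge" %in% sig$cancer_list)
  expect_true("core" %in% sig$cancer_list)
})

test_that("pathway-frequency selection equals brute-force recomputation on random instances", {
  set.seed(23)
  for (rep in 1:10) {
    universe <- sprintf("g%02d", 1:30)
    n_datasets <- 3L
    n_sets <- sample(3:8, 1)
    sets <- lapply(seq_len(n_sets), function(i) sample(universe, sample(5:15, 1)))
    names(sets) <- sprintf("S%d", seq_len(n_sets))
    enr <- list()
    for (d in seq_len(n_datasets)) {
      res <- data.frame(set = names(sets), size = lengths(sets),
                        es = runif(n_sets, -1, 1), nes = 0,
                        p_perm = 0.01, fdr_q = runif(n_sets, 0, 0.2),
                        n_perm = 100L, stringsAsFactors = FALSE)
      res$leading_edge <- lapply(sets, function(s) {
        s[seq_len(sample(length(s), 1))]
      })
      enr[[d]] <- list(dataset_id = sprintf("d%d", d), cell_type = "cancer",
                       result = res)
    }
    params <- derivation_params()
    sig <- suppressWarnings(derive_frequency_signature(enr, sets, params))

    # brute force: per dataset, count memberships by exhaustive loops
    per_ds <- lapply(enr, function(e) {
      res <- e$result
      enriched <- which(res$fdr_q < 0.05 & res$es > 0)
      if (!length(enriched)) return(character())
      pool <- unique(unlist(res$leading_edge[enriched]))
      need <- ceiling(0.2 * length(enriched))
      kept <- character()
      for (g in pool) {
        cnt <- 0L
        for (j in enriched) if (g %in% sets[[res$set[j]]]) cnt <- cnt + 1L
        if (cnt >= need) kept <- c(kept, g)
      }
      kept
    })
    expect_setequal(sig$cancer_list, Reduce(intersect, per_ds))
  }
})

test_that("tightening frequency or FDR thresholds never enlarges the gene list", {
  cfg <- coculture_sim_config(seed = 41)
  exps <- simulate_coculture_experiments(cfg)
  sets <- simulate_gene_set_collection(cfg$genes, names(cfg$planted_program),
                                       seed = 41)
  enr <- lapply(exps[1:3], function(e) {
    list(dataset_id = e$dataset_id, cell_type = e$cell_type,
         result = gsea(rank_by_tstat(e), sets, n_perm = 200, seed = 41))
  })
  base <- suppressWarnings(derive_frequency_signature(enr, sets,
    derivation_params(fdr_threshold = 0.25, pathway_frequency_threshold = 0.2)))
  tighter_freq <- suppressWarnings(derive_frequency_signature(enr, sets,
    derivation_params(fdr_threshold = 0.25, pathway_frequency_threshold = 0.6)))
  tighter_fdr <- suppressWarnings(derive_frequency_signature(enr, sets,
    derivation_params(fdr_threshold = 0.01, pathway_frequency_threshold = 0.2)))
  expect_true(all(tighter_freq$genes %in% base$genes))
  expect_true(all(tighter_fdr$genes %in% base$genes))
})

test_that("fold-change selection is inclusive at 1.5 and requires all datasets", {
  mk <- function(id, ct, co_vals) {
    vals <- rbind(boundary = c(2, 2, co_vals[1], co_vals[1]),
                  partial = c(2, 2, co_vals[2], co_vals[2]),
                  null = c(2, 2, 2, 2))
    colnames(vals) <- sprintf("%s_s%d", id, 1:4)
    culture_experiment(id, ct, expression_matrix(vals, "linear"),
                       c("mono", "mono", "co", "co"))
  }
  # boundary gene at exactly 1.5x in all three cancer datasets: selected;
  # partial gene above threshold in only 2 of 3: excluded
  exps <- list(mk("d1", "cancer", c(3, 4)), mk("d2", "cancer", c(3, 4)),
               mk("d3", "cancer", c(3, 2)),
               mk("d1", "caf", c(2, 2)), mk("d2", "caf", c(2, 2)),
               mk("d3", "caf", c(2, 2)))
  sig <- derive_foldchange_signature(exps)
  expect_identical(sig$cancer_list, "boundary")
  expect_false("partial" %in% sig$genes)
  expect_false("null" %in% sig$genes)
})

test_that("signature scoring equals the mean of per-gene z-scores", {
  set.seed(3)
  vals <- matrix(rexp(10 * 5, 0.1), nrow = 10,
                 dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:5)))
  em <- expression_matrix(vals, "linear")
  sig_genes <- c("g01", "g04", "g07")
  scores <- score_signature(em, sig_genes)

  logm <- log2(vals + 1)
  z <- sapply(sig_genes, function(g) (logm[g, ] - mean(logm[g, ])) / sd(logm[g, ]))
  expect_equal(unname(scores), unname(rowMeans(z)), tolerance = 1e-9)

  # single-gene signature is that gene's z-score
  s1 <- score_signature(em, "g02")
  expect_equal(unname(s1),
               unname((logm["g02", ] - mean(logm["g02", ])) / sd(logm["g02", ])),
               tolerance = 1e-12)

  # constant matrix scores 0 everywhere
  cm <- expression_matrix(matrix(5, 3, 4, dimnames = list(c("a", "b", "c"),
                                                          sprintf("s%d", 1:4))),
                          "linear")
  expect_equal(unname(score_signature(cm, c("a", "b"))), rep(0, 4))

  expect_error(score_signature(em, c("nope1", "nope2")), "no signature genes")
})

test_that("signature scores are invariant under gene-wise affine transforms of log expression", {
  set.seed(5)
  logm <- matrix(rnorm(8 * 6, mean = 5), nrow = 8,
                 dimnames = list(sprintf("g%d", 1:8), sprintf("s%d", 1:6)))
  em1 <- expression_matrix(logm, "log2p1")
  shifted <- logm * runif(8, 0.5, 2) + runif(8, -1, 1)  # per-gene affine
  em2 <- expression_matrix(shifted, "log2p1")
  genes <- c("g1", "g3", "g8")
  expect_equal(score_signature(em1, genes), score_signature(em2, genes),
               tolerance = 1e-9)
})

test_that("signature JSON round-trips", {
  sig <- signature_definition("demo", c("A", "B"), c("B", "C", "D"))
  path <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_identical(back$genes, sig$genes)
  expect_identical(back$cancer_list, sig$cancer_list)
  expect_identical(back$caf_list, sig$caf_list)
})
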