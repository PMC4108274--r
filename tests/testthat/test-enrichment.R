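make_ann <- function(df, names = character(0)) annotation_set(df, names)

test_that("hypergeometric tail matches the closed form and enumeration", {
  # all 5 cluster genes annotated, 5 annotated among 100 -> p = 1/C(100,5)
  bg <- sprintf("g%03d", 1:100)
  ann <- make_ann(data.frame(probeset_id = bg[1:5], term_id = "GO:T",
                             namespace = "BP"))
  enr <- hypergeom_enrich(list(c1 = bg[1:5]), ann, bg, universe = "all")
  expect_equal(enr$p, 1 / choose(100, 5), tolerance = 1e-12)
  expect_identical(enr$n_in_cluster, 5L)
  # exhaustive enumeration oracle on universes <= 15
  set.seed(8)
  for (rep in 1:20) {
    nn <- sample(8:15, 1)
    kk <- sample(2:(nn - 1), 1)
    dr <- sample(2:(nn - 1), 1)
    bg2 <- sprintf("u%02d", seq_len(nn))
    ann2 <- make_ann(data.frame(probeset_id = bg2[seq_len(kk)],
                                term_id = "GO:E", namespace = "MF"))
    cluster <- sample(bg2, dr)
    x <- sum(cluster %in% bg2[seq_len(kk)])
    if (x == 0) next
    enr2 <- hypergeom_enrich(list(c = cluster), ann2, bg2, universe = "all")
    expect_equal(enr2$p, oracle_hyper_tail(x, kk, nn, dr), tolerance = 1e-12)
  }
})

test_that("a term annotating every background gene has p = 1", {
  bg <- sprintf("g%02d", 1:30)
  ann <- make_ann(data.frame(probeset_id = bg, term_id = "GO:ALL",
                             namespace = "BP"))
  enr <- hypergeom_enrich(list(c1 = bg[1:6]), ann, bg)
  expect_equal(enr$p, 1)
  expect_false(enr$significant)  # p = 1 can never pass FDR
})

test_that("significance requires both FDR < 0.05 and >= 2 annotated genes", {
  bg <- sprintf("g%03d", 1:200)
  ann <- make_ann(data.frame(probeset_id = bg[1],
                             term_id = "GO:ONE", namespace = "BP"))
  # single-gene term inside a tiny cluster: p is small but n_in_cluster = 1
  enr <- hypergeom_enrich(list(c1 = bg[1:2]), ann, bg, universe = "all")
  row <- enr[enr$term_id == "GO:ONE", ]
  expect_lt(row$fdr, 0.05)
  expect_identical(row$n_in_cluster, 1L)
  expect_false(row$significant)
})

test_that("BH adjustment within cluster x namespace matches the step-up procedure", {
  set.seed(5)
  bg <- sprintf("g%03d", 1:80)
  rows <- do.call(rbind, lapply(1:12, function(t) {
    data.frame(probeset_id = sample(bg, sample(4:20, 1)),
               term_id = sprintf("GO:%02d", t),
               namespace = if (t <= 6) "BP" else "MF")
  }))
  ann <- make_ann(rows)
  cluster <- sample(bg, 15)
  enr <- hypergeom_enrich(list(c1 = cluster), ann, bg)
  for (ns in unique(enr$namespace)) {
    sub <- enr[enr$namespace == ns, ]
    expect_equal(sub$fdr, oracle_bh(sub$p), tolerance = 1e-12)
  }
})

test_that("universe restriction to annotated probesets changes the background size", {
  bg <- sprintf("g%03d", 1:100)
  ann <- make_ann(data.frame(probeset_id = bg[1:40],
                             term_id = rep(c("GO:A", "GO:B"), each = 20),
                             namespace = "BP"))
  e_ann <- hypergeom_enrich(list(c1 = bg[1:10]), ann, bg, universe = "annotated")
  e_all <- hypergeom_enrich(list(c1 = bg[1:10]), ann, bg, universe = "all")
  expect_identical(unique(e_ann$background_size), 40L)
  expect_identical(unique(e_all$background_size), 100L)
  expect_true(all(e_ann$p >= e_all$p - 1e-12))
  expect_error(hypergeom_enrich(list(c1 = c("nope", bg[1:3])), ann, bg),
               "outside the background")
})

test_that("guide enrichment includes the guide and matches the generic path", {
  sim <- simulate_compendium(n_genes = 60, n_arrays = 20,
                             modules = list(module_spec(8)), seed = 3)
  gcl <- guide_clusters(hrr_network(sim$expr), k = 10)
  bg <- rownames(sim$expr)
  guide <- gcl$probeset_ids[1]
  e1 <- guide_enrichment(gcl, sim$annotations, bg, guides = guide)
  members <- c(guide, guide_cluster(gcl, guide)$probeset_id)
  e2 <- hypergeom_enrich(stats::setNames(list(members), guide),
                         sim$annotations, bg)
  expect_equal(e1$p, e2$p)
  expect_identical(e1$term_id, e2$term_id)
  expect_error(guide_enrichment(gcl, sim$annotations, bg, guides = "zz"),
               "unknown guide")
})

test_that("performance metrics follow the harmonic-mean definition", {
  # every module enriched and every annotation hit -> all three are 1
  bg <- sprintf("g%02d", 1:40)
  ann <- make_ann(data.frame(probeset_id = bg[1:10],
                             term_id = rep(c("GO:A", "GO:B"), each = 5),
                             namespace = "BP"))
  perf <- clustering_performance(list(c1 = bg[1:5], c2 = bg[6:10]), ann, bg)
  expect_equal(perf$specificity, 1)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$f_measure, 1)
  # spec 0.5 / sens 0.25 -> F = 1/3 (direct harmonic mean identity)
  expect_equal(2 * 0.5 * 0.25 / (0.5 + 0.25), 1 / 3)
  # no significant enrichment anywhere -> F = 0 by convention
  set.seed(2)
  ann0 <- make_ann(data.frame(probeset_id = sample(bg, 20),
                              term_id = sample(sprintf("GO:%d", 1:8), 20,
                                               replace = TRUE),
                              namespace = "BP"))
  perf0 <- clustering_performance(list(c1 = bg[c(1, 12, 23, 34)]), ann0, bg)
  if (perf0$specificity == 0) expect_identical(perf0$f_measure, 0)
  expect_error(clustering_performance(list(c1 = bg[1:3]), ann,
                                      background = "h99"),
               "no annotated")
})

test_that("shuffled annotations rarely produce significant clusters", {
  set.seed(77)
  bg <- sprintf("g%03d", 1:150)
  clusters <- split(bg[1:60], rep(1:6, each = 10))
  hits <- 0L; total <- 0L
  for (rep in 1:6) {
    rows <- data.frame(probeset_id = sample(bg, 120, replace = TRUE),
                       term_id = sample(sprintf("GO:%02d", 1:10), 120,
                                        replace = TRUE),
                       namespace = "BP")
    enr <- hypergeom_enrich(clusters, make_ann(rows), bg)
    sig <- unique(enr$cluster_id[enr$significant])
    hits <- hits + length(sig)
    total <- total + length(clusters)
  }
  expect_lte(hits / total, 0.15)  # generous bound around the 5% level
})

test_that("enrichment tables are written with the standard report columns", {
  sim <- simulate_compendium(n_genes = 80, n_arrays = 20,
                             modules = list(module_spec(10)), seed = 5)
  net <- hrr_network(sim$expr)
  cl <- suppressWarnings(mcl(threshold_network(net, 10), inflation = 2))
  enr <- hypergeom_enrich(cl, sim$annotations, rownames(sim$expr))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(enr, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_true(all(c("cluster_id", "term_id", "n_in_cluster", "n_in_background",
                    "p", "fdr", "description") %in% colnames(back)))
})
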