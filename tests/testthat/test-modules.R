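test_that("average-linkage tree: block structure and the naive oracle", {
  # two zero-distance blocks separated by distance 1
  d <- matrix(1, 6, 6)
  d[1:3, 1:3] <- 0
  d[4:6, 4:6] <- 0
  diag(d) <- 0
  dimnames(d) <- list(paste0("g", 1:6), paste0("g", 1:6))
  tree <- hierarchical_tree(d)
  expect_equal(min(tree$height), 0)
  expect_equal(max(tree$height), 1)

  set.seed(20)
  for (i in 1:100) {
    d <- random_dissimilarity(7)
    tree <- hierarchical_tree(d)
    expect_equal(sort(tree$height), oracle_average_linkage_heights(d),
                 tolerance = 1e-10)
  }
})

test_that("tree heights are invariant under leaf permutation", {
  set.seed(21)
  d <- random_dissimilarity(9)
  perm <- sample(9)
  t1 <- hierarchical_tree(d)
  t2 <- hierarchical_tree(d[perm, perm])
  expect_equal(sort(t1$height), sort(t2$height), tolerance = 1e-10)
})

test_that("tree input validation", {
  d <- random_dissimilarity(4)
  d[1, 2] <- d[1, 2] + 1          # asymmetric
  expect_error(hierarchical_tree(d), "symmetric")
})

block_dissimilarity <- function(sizes, within = 0.1, between = 0.9) {
  n <- sum(sizes)
  d <- matrix(between, n, n)
  start <- cumsum(c(1, sizes))
  for (b in seq_along(sizes)) {
    idx <- start[b]:(start[b + 1] - 1)
    d[idx, idx] <- within
  }
  diag(d) <- 0
  dimnames(d) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  d
}

test_that("dynamic tree cut recovers planted blocks and enforces min size", {
  d <- block_dissimilarity(c(50, 50))
  labels <- dynamic_tree_cut(hierarchical_tree(d), min_size = 30)
  expect_setequal(setdiff(unique(labels), "unassigned"), c("M1", "M2"))
  expect_equal(sum(labels == "unassigned"), 0)
  expect_equal(unname(table(labels)[c("M1", "M2")]), c(50L, 50L),
               ignore_attr = TRUE)

  # a 10-gene block cannot reach min_size 30
  d2 <- block_dissimilarity(c(50, 10))
  lab2 <- dynamic_tree_cut(hierarchical_tree(d2), min_size = 30)
  small <- sprintf("g%03d", 51:60)
  expect_true(all(lab2[small] == "unassigned"))

  # single homogeneous block below the cut -> one module with all genes
  d3 <- block_dissimilarity(60)
  lab3 <- dynamic_tree_cut(hierarchical_tree(d3), min_size = 30,
                           cut_height = 0.5)
  expect_true(all(lab3 == "M1"))

  expect_error(dynamic_tree_cut(hierarchical_tree(d3), min_size = 1), "min_size")
})

test_that("eigengenes: identical genes, the 2-gene closed form, sign contract", {
  set.seed(22)
  n <- 30
  profile <- rnorm(n)
  vals <- rbind(g1 = 2 * profile + 5, g2 = 3 * profile - 1, g3 = profile)
  colnames(vals) <- sprintf("s%02d", 1:n)
  em <- quick_em(vals)
  labels <- setNames(rep("M1", 3), rownames(vals))
  me <- module_eigengenes(em, labels)
  expect_equal(unname(me$prop_var_explained["M1"]), 1, tolerance = 1e-10)
  zs <- (profile - mean(profile)) / sd(profile)
  expect_equal(abs(cor(me$eigengenes[, "M1"], zs)), 1, tolerance = 1e-10)
  expect_equal(sum(me$eigengenes[, "M1"]^2), 1, tolerance = 1e-10)

  # 2-gene module: prop_var = (1 + |rho|) / 2
  for (i in 1:5) {
    v2 <- matrix(rnorm(2 * n), 2, n,
                 dimnames = list(c("a", "b"), sprintf("s%02d", 1:n)))
    rho <- cor(v2[1, ], v2[2, ])
    me2 <- module_eigengenes(quick_em(v2), setNames(c("M1", "M1"), c("a", "b")))
    expect_equal(unname(me2$prop_var_explained["M1"]), (1 + abs(rho)) / 2,
                 tolerance = 1e-10)
  }

  # sign convention: mean correlation of members with their ME is >= 0
  set.seed(23)
  vals <- matrix(rnorm(20 * 15), 20, 15,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:15)))
  lab <- setNames(rep(c("M1", "M2"), each = 10), rownames(vals))
  me3 <- module_eigengenes(quick_em(vals), lab)
  mm <- module_membership(quick_em(vals), me3$eigengenes)
  expect_gte(mean(mm[names(lab)[lab == "M1"], "M1"]), 0)
  expect_gte(mean(mm[names(lab)[lab == "M2"], "M2"]), 0)
})

test_that("modules driven by the same factor merge; distinct factors do not", {
  set.seed(24)
  n <- 80
  f <- rnorm(n)
  g <- rnorm(n)                      # independent factor
  mk <- function(fac, k, lam = 0.9)
    t(sapply(seq_len(k), function(i) lam * fac + sqrt(1 - lam^2) * rnorm(n)))
  vals <- rbind(mk(f, 40), mk(f, 35), mk(g, 30))
  dimnames(vals) <- list(sprintf("g%03d", seq_len(nrow(vals))),
                         sprintf("s%03d", 1:n))
  em <- quick_em(vals)
  labels <- setNames(rep(c("M1", "M2", "M3"), c(40, 35, 30)), rownames(vals))
  me <- module_eigengenes(em, labels)
  expect_gt(abs(cor(me$eigengenes[, "M1"], me$eigengenes[, "M2"])), 0.95)

  merged <- merge_close_modules(em, labels, merge_height = 0.1)
  mods <- setdiff(unique(merged$labels), "unassigned")
  expect_length(mods, 2)
  # M1 and M2 became one module keeping the larger label, M3 untouched
  expect_equal(unname(merged$labels["g001"]), unname(merged$labels["g041"]))
  expect_false(unname(merged$labels["g001"]) == unname(merged$labels["g076"]))

  # fixed point: re-running changes nothing
  again <- merge_close_modules(em, merged$labels, merge_height = 0.1)
  expect_identical(again$labels, merged$labels)
})

test_that("moderately correlated modules are not merged", {
  set.seed(25)
  n <- 100
  f <- rnorm(n)
  g <- sqrt(0.25) * f + sqrt(0.75) * rnorm(n)   # factor correlation 0.5
  mk <- function(fac, k, lam = 0.95)
    t(sapply(seq_len(k), function(i) lam * fac + sqrt(1 - lam^2) * rnorm(n)))
  vals <- rbind(mk(f, 30), mk(g, 30))
  dimnames(vals) <- list(sprintf("g%03d", 1:60), sprintf("s%03d", 1:n))
  em <- quick_em(vals)
  labels <- setNames(rep(c("M1", "M2"), each = 30), rownames(vals))
  merged <- merge_close_modules(em, labels, merge_height = 0.1)
  expect_identical(merged$labels, labels)
})

test_that("module membership equals direct correlation with the eigengene", {
  set.seed(26)
  vals <- matrix(rnorm(20 * 12), 20, 12,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:12)))
  em <- quick_em(vals)
  lab <- setNames(rep(c("M1", "M2", "M3", "M4", "M5"), each = 4), rownames(vals))
  me <- module_eigengenes(em, lab)
  mm <- module_membership(em, me$eigengenes)
  for (g in rownames(vals)) for (m in colnames(me$eigengenes))
    expect_equal(mm[g, m], cor(vals[g, ], me$eigengenes[, m]),
                 tolerance = 1e-12)

  # a gene exactly equal to an ME has MM 1; its negation -1
  vals2 <- rbind(vals, gme = me$eigengenes[, "M1"],
                 gneg = -me$eigengenes[, "M1"])
  mm2 <- module_membership(quick_em(vals2), me$eigengenes)
  expect_equal(mm2["gme", "M1"], 1, tolerance = 1e-12)
  expect_equal(mm2["gneg", "M1"], -1, tolerance = 1e-12)
})

test_that("membership quantiles follow the rank definition", {
  set.seed(27)
  size <- 100
  n <- 30
  f <- rnorm(n)
  lam <- seq(0.95, 0.05, length.out = size)
  vals <- t(sapply(lam, function(l) l * f + sqrt(1 - l^2) * rnorm(n)))
  dimnames(vals) <- list(sprintf("g%03d", 1:size), sprintf("s%03d", 1:n))
  em <- quick_em(vals)
  lab <- setNames(rep("M1", size), rownames(vals))
  me <- module_eigengenes(em, lab)
  mm <- module_membership(em, me$eigengenes)
  q <- mm_quantiles(mm, lab)
  top <- names(which.max(mm[, "M1"]))
  bottom <- names(which.min(mm[, "M1"]))
  expect_equal(unname(q[top]), 1 - 1 / size)
  expect_equal(mm_quantile(mm, lab, top, "M1"), 0.99)
  expect_equal(unname(q[bottom]), 0)
  expect_error(mm_quantile(mm, lab, "nosuch", "M1"), "not a member")
  # quantiles are a permutation of (0, 1/size, ..., 1 - 1/size)
  expect_equal(sort(unname(q)), (0:(size - 1)) / size)
})

test_that("hub calling across regions honours quantile and region thresholds", {
  # 8 regions, module planted in 6 of them with the seed gene at top loading
  cfg <- sim_config(n_regions = 8, n_samples_per_region = 60, n_genes = 300,
                    modules = list(module_spec(60, c(0.5, 0.85), 1:6,
                                               seed_gene_loading = 0.98)),
                    seed = 30)
  sim <- generate_multiregion_dataset(cfg)
  mm_list <- vector("list", 8); labels_list <- vector("list", 8)
  for (r in 1:8) {
    m <- sim$matrices[[r]]
    det <- detect_modules(m, build_network(m))
    mm_list[r] <- list(det$MM)
    labels_list[[r]] <- det$labels
  }
  hubs <- hub_genes(mm_list, labels_list, q = 0.90, min_regions = 5)
  expect_true(sim$truth$seed_gene %in% hubs)

  # min_regions above the number of regions -> nothing qualifies
  expect_length(hub_genes(mm_list, labels_list, q = 0.90, min_regions = 9), 0)

  # q = 0: every gene assigned in >= min_regions regions is returned
  all0 <- hub_genes(mm_list, labels_list, q = 0, min_regions = 8)
  assigned_everywhere <- Reduce(intersect, lapply(labels_list, function(l)
    names(l)[l != "unassigned"]))
  expect_setequal(all0, assigned_everywhere)
})

test_that("core set: quantile boundaries and planted top loadings", {
  cfg <- sim_config(n_regions = 2, n_samples_per_region = 80, n_genes = 200,
                    modules = list(module_spec(100, c(0.6, 0.9), 1:2)),
                    seed = 31)
  sim <- generate_multiregion_dataset(cfg)
  mm_list <- list(); labels_list <- list()
  for (r in 1:2) {
    m <- sim$matrices[[r]]
    det <- detect_modules(m, build_network(m))
    mm_list[[r]] <- det$MM
    labels_list[[r]] <- det$labels
  }
  targets <- vapply(labels_list, function(l) unname(l[["g0001"]]), character(1))

  expect_length(core_set(mm_list, labels_list, targets, q = 1), 0)
  all_members <- sort(unique(unlist(lapply(seq_along(labels_list), function(i)
    names(labels_list[[i]])[labels_list[[i]] == targets[i]]))))
  expect_setequal(core_set(mm_list, labels_list, targets, q = 0), all_members)

  core <- core_set(mm_list, labels_list, targets, q = 0.80)
  # the highest-loading planted genes should be in the core
  lam <- sort(sim$truth$loadings[sim$truth$module_genes$M1], decreasing = TRUE)
  top <- names(lam)[1:10]
  expect_true(all(top %in% core))

  expect_warning(core_set(mm_list, labels_list, c("Mx", targets[2]), q = 0.8),
                 "absent")
})

test_that("detected labels partition genes and respect min_size", {
  sim <- shared_module_sim(n_genes = 200, n_samples = 50, mod_size = 60,
                           seed = 32, n_regions = 1)
  m <- sim$matrices[[1]]
  det <- detect_modules(m, build_network(m), min_size = 30)
  expect_length(det$labels, 200)
  sizes <- table(det$labels[det$labels != "unassigned"])
  expect_true(all(sizes >= 30))
  # every module's top-MM member has quantile 1 - 1/size
  for (mod in names(sizes)) {
    members <- names(det$labels)[det$labels == mod]
    top <- members[which.max(det$MM[members, mod])]
    expect_equal(unname(det$mm_quantile[top]), 1 - 1 / length(members))
  }
})
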