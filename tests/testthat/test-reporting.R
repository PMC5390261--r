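test_that("category assignment uses the map with an Unknown-function default", {
  map <- fixture_category_map(c("cell_down", "secretome_down"))
  tab <- data.frame(gene = c("TUBB2A", "FN1", "NOVEL1"),
                    stringsAsFactors = FALSE)
  ann <- assign_categories(tab, map)
  expect_equal(ann$category,
               c("Cytoskeletal", "Extracellular matrix", "Unknown function"))
})

test_that("category percentages use half-up one-decimal rounding", {
  tab <- data.frame(category = c(rep("Drug resistance", 2),
                                 "Protein transport",
                                 rep("Other", 15)))
  dist <- category_distribution(tab)  # 18 rows
  expect_equal(dist$percent[dist$category == "Drug resistance"], 11.1)
  expect_equal(dist$percent[dist$category == "Protein transport"], 5.6)

  one <- category_distribution(data.frame(category = rep("A", 7)))
  expect_equal(one$percent, 100.0)

  expect_error(category_distribution(tab[0, , drop = FALSE]), "empty")

  # percentages sum to 100 within rounding slack on every fixture; half-up
  # rounding can drift by at most 0.05 points per category
  for (nm in c("cell_down", "cell_up", "secretome_down", "secretome_up",
               "xenograft_down", "xenograft_up")) {
    d <- category_distribution(curated_fixture(nm))
    expect_lt(abs(sum(d$percent) - 100),
              max(0.3, 0.05 * nrow(d)) + 1e-9)
  }
})

test_that("extreme-protein ranking reproduces the published table leaders", {
  cases <- list(cell_down = c("TUBB2A", -42.9),
                cell_up = c("PLS1", 7.1),
                secretome_down = c("FN1", -15.3),
                secretome_up = c("HBB", 5.0),
                xenograft_down = c("TUBB2A", -78.1),
                xenograft_up = c("POTEF", 23.0))
  for (nm in names(cases)) {
    tab <- curated_fixture(nm)
    top <- rank_extremes(tab)
    expect_equal(top$gene, cases[[nm]][1], info = nm)
    expect_equal(top$rsc, as.numeric(cases[[nm]][2]), info = nm)
    # invariant to row order
    perm <- tab[rev(seq_len(nrow(tab))), ]
    attr(perm, "direction") <- attr(tab, "direction")
    expect_equal(rank_extremes(perm)$gene, top$gene)
  }
  single <- data.frame(gene = "X", rsc = 1.0)
  expect_equal(rank_extremes(single, "up")$gene, "X")
  expect_error(rank_extremes(single[0, ], "up"), "empty")
})

test_that("sample correlations match the textbook Pearson formula", {
  set.seed(30)
  m <- matrix(rpois(24, 30) + 1, 6, 4)
  colnames(m) <- paste0("s", 1:4); rownames(m) <- paste0("p", 1:6)
  r <- sample_correlation_matrix(m)
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (a in 1:4) for (b in 1:4)
    expect_equal(r[a, b], if (a == b) 1 else pearson(m[, a], m[, b]),
                 tolerance = 1e-12)
  expect_identical(r, t(r))
  expect_true(all(eigen(r, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))

  # perfect anticorrelation
  x <- c(1, 4, 2, 9, 5)
  m2 <- cbind(s1 = x, s2 = 10 - x)
  rownames(m2) <- paste0("p", 1:5)
  expect_equal(sample_correlation_matrix(m2)["s1", "s2"], -1)

  m3 <- cbind(s1 = x, s2 = rep(3, 5))
  rownames(m3) <- paste0("p", 1:5)
  expect_error(sample_correlation_matrix(m3), "s2")
})

test_that("average-linkage clustering matches the brute-force oracle", {
  # identical samples merge first at height 0
  set.seed(41)
  base <- runif(10)
  m <- cbind(a = base, b = base, c = runif(10), d = runif(10))
  rownames(m) <- paste0("p", 1:10)
  r <- sample_correlation_matrix(m)
  cl <- hierarchical_cluster(r)
  first <- sort(cl$hclust$labels[-cl$hclust$merge[1, ]])
  expect_equal(first, c("a", "b"))
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)

  # forced topology: highly correlated pair stays adjacent in the leaf order
  r3 <- matrix(c(1, 0.99, 0.1,
                 0.99, 1, 0.1,
                 0.1, 0.1, 1), 3, 3,
               dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  ord <- hierarchical_cluster(r3)$order
  expect_equal(abs(diff(match(c("s1", "s2"), ord))), 1)

  # merge heights equal exhaustive UPGMA on a 6-sample matrix
  set.seed(55)
  m6 <- matrix(rpois(60, 25), 10, 6,
               dimnames = list(paste0("p", 1:10), paste0("s", 1:6)))
  r6 <- sample_correlation_matrix(m6)
  cl6 <- hierarchical_cluster(r6)
  expect_equal(cl6$hclust$height, oracle_average_linkage(1 - r6),
               tolerance = 1e-12)
  expect_equal(sort(rownames(cl6$matrix)), sort(colnames(r6)))

  bad <- r3; bad[1, 2] <- 0.5
  expect_error(hierarchical_cluster(bad), "symmetric")
})

test_that("gene-list export writes deduplicated one-symbol-per-line files", {
  dir <- withr::local_tempdir()
  tabs <- list(cell_down = curated_fixture("cell_down"),
               dup = data.frame(gene = c("A", "B", "A")),
               empty = data.frame(gene = character(0)))
  paths <- export_gene_lists(tabs, dir)
  genes <- readLines(file.path(dir, "genes_cell_down.txt"))
  expect_equal(genes, unique(curated_fixture("cell_down")$gene))
  expect_equal(readLines(file.path(dir, "genes_dup.txt")), c("A", "B"))
  expect_equal(length(readLines(file.path(dir, "genes_empty.txt"))), 0L)
})
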