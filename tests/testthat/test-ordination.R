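test_that("chord transform scales rows to unit norm", {
  expect_equal(unname(chordTransform(rbind(c(0.6, 0.8)))), rbind(c(0.6, 0.8)))
  expect_equal(unname(chordTransform(rbind(c(3, 4)))), rbind(c(0.6, 0.8)))
  set.seed(1)
  m <- matrix(runif(40), 8, 5)
  expect_true(all(abs(rowSums(chordTransform(m)^2) - 1) < 1e-12))
  expect_error(chordTransform(rbind(s1 = c(1, 1), s2 = c(0, 0))), "s2")
})

test_that("PCA matches an independent eigensolver and handles edge shapes", {
  # collinear points: PC1 carries all variance
  res <- pcaOrdination(rbind(c(0, 0), c(1, 1), c(2, 2)), 1)
  expect_equal(res@explained, 1)
  # duplicated rows give identical score rows
  m <- rbind(a = c(1, 2, 3), b = c(4, 0, 1), a2 = c(1, 2, 3), c = c(2, 2, 2))
  sc <- pcaOrdination(m, 2)@scores
  expect_equal(sc["a", ], sc["a2", ])
  # 5x4 random fixture vs prcomp (svd-based, independent code path)
  set.seed(7)
  x <- matrix(rnorm(20), 5, 4)
  mine <- pcaOrdination(x, 3)
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  for (j in 1:3) {
    s <- sign(sum(mine@scores[, j] * pr$x[, j]))
    expect_equal(unname(mine@scores[, j]), unname(s * pr$x[, j]),
                 tolerance = 1e-10)
  }
  expect_equal(mine@explained, (pr$sdev^2 / sum(pr$sdev^2))[1:3],
               tolerance = 1e-10)
  expect_error(pcaOrdination(x, 5), "nAxes")
  # sign convention: largest-magnitude loading positive
  for (j in 1:3) {
    l <- mine@loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("Bray-Curtis matches hand computations and metric properties", {
  expect_equal(as.matrix(brayCurtis(rbind(c(1, 2), c(1, 2))))[1, 2], 0)
  expect_equal(as.matrix(brayCurtis(rbind(c(5, 5, 0, 0), c(0, 0, 5, 5))))[1, 2], 1)
  # 1 - 2*4/20 = 0.6
  expect_equal(as.matrix(brayCurtis(rbind(c(5, 5, 0, 0), c(2, 2, 3, 3))))[1, 2], 0.6)
  set.seed(3)
  m <- matrix(rpois(60, 5), 6, 10)
  d <- as.matrix(brayCurtis(m))
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(diag(d) == 0))
  expect_warning(d0 <- brayCurtis(rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))),
                 "all-zero")
  expect_equal(as.matrix(d0)["a", "b"], 0)
  expect_equal(as.matrix(d0)["a", "c"], 1)
})

test_that("PCoA recovers Euclidean geometry and reports negative eigenvalues", {
  # 3 collinear points at 0, 1, 3
  d <- dist(c(0, 1, 3))
  res <- suppressWarnings(pcoaOrdination(d, 1))
  eps <- sqrt(.Machine$double.eps) * max(abs(res@eigenvalues))
  expect_equal(sum(res@eigenvalues > eps), 1L)
  expect_equal(as.numeric(dist(res@scores[, 1])), as.numeric(d),
               tolerance = 1e-10)
  # Bray-Curtis on a 4-sample fixture is non-Euclidean: negative eigenvalue
  cnt <- rbind(c(5, 5, 0, 0), c(0, 0, 5, 5), c(3, 3, 3, 1), c(1, 4, 4, 1))
  resb <- pcoaOrdination(brayCurtis(cnt), 2)
  expect_true(any(resb@eigenvalues < -1e-10))
  pos <- resb@eigenvalues[resb@eigenvalues > 0]
  expect_equal(resb@explained, pos[1:2] / sum(pos))
  expect_warning(pcoaOrdination(brayCurtis(cnt), 4), "positive eigenvalue")
})

test_that("chord-PCA and PCoA of Euclidean distances agree axis by axis", {
  set.seed(11)
  for (rep in 1:3) {
    m <- chordTransform(matrix(runif(9 * 6), 9, 6))
    p1 <- pcaOrdination(m, 3)@scores
    p2 <- pcoaOrdination(dist(m), 3)@scores
    for (j in 1:3) {
      s <- sign(sum(p1[, j] * p2[, j]))
      expect_lt(max(abs(p1[, j] - s * p2[, j])), 1e-8)
    }
  }
})

test_that("Hill numbers match hand values, limits and bounds", {
  expect_equal(unname(hillDiversity(rbind(rep(0.25, 4)), 2)), 4)
  expect_equal(unname(hillDiversity(rbind(c(1, 0, 0)), 2)), 1)
  expect_equal(unname(hillDiversity(rbind(c(0.2, 0.2, 0.3, 0.3)), 2)),
               1 / 0.26)
  # q = 1 equals exponentiated Shannon entropy
  p <- c(0.5, 0.3, 0.2)
  expect_equal(unname(hillDiversity(rbind(p), 1)), exp(-sum(p * log(p))))
  # q = 0 is richness; zero-abundance OTUs are excluded
  expect_equal(unname(hillDiversity(rbind(c(0.7, 0.3, 0)), 0)), 2)
  # agrees with vegan's inverse Simpson at q = 2
  set.seed(5)
  rel <- matrix(runif(30), 5, 6)
  rel <- rel / rowSums(rel)
  expect_equal(unname(hillDiversity(rel, 2)),
               unname(vegan::diversity(rel, "invsimpson")), tolerance = 1e-12)
  # bounds: 1 <= 2D <= S
  expect_true(all(hillDiversity(rel, 2) >= 1 & hillDiversity(rel, 2) <= 6))
  expect_error(hillDiversity(rbind(c(-0.1, 1.1)), 2), "non-negative")
})

test_that("UPGMA heights, ultrametricity and agreement with brute force", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr <- upgmaTree(as.dist(d))
  expect_equal(sort(tr$hclust$height / 2), c(1, 3)) # node heights
  depths <- ape::node.depth.edgelength(tr$phylo)
  expect_equal(unname(depths[1:3]), rep(3, 3)) # ultrametric leaves
  # all-equal distances: every merge at the same height
  de <- matrix(1, 4, 4); diag(de) <- 0
  tre <- upgmaTree(as.dist(de))
  expect_true(all(abs(tre$hclust$height - 1) < 1e-12))
  # 5-sample fixture against the brute-force oracle
  set.seed(9)
  m <- matrix(rpois(25, 8), 5, 5)
  dd <- brayCurtis(m)
  tr5 <- upgmaTree(dd)
  oracle <- bruteUpgma(dd)
  expect_equal(tr5$hclust$height, oracle$heights, tolerance = 1e-12)
  merged <- lapply(seq_len(nrow(tr5$hclust$merge)), function(k) {
    collect <- function(i) {
      if (i < 0) return(-i)
      unlist(lapply(tr5$hclust$merge[i, ], collect))
    }
    sort(unlist(lapply(tr5$hclust$merge[k, ], collect)))
  })
  expect_equal(merged, oracle$members)
  # ultrametric property: two largest cophenetic distances of a triple equal
  cop <- as.matrix(stats::cophenetic(tr5$hclust))
  for (tri in utils::combn(5, 3, simplify = FALSE)) {
    v <- sort(c(cop[tri[1], tri[2]], cop[tri[1], tri[3]],
                cop[tri[2], tri[3]]))
    expect_equal(v[2], v[3], tolerance = 1e-12)
  }
})
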