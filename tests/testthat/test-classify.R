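test_that("two-tier significance rule matches the anchored examples and is monotone", {
  expect_equal(unname(call_significance(rbind(c(0.04, 0.09, 0.2)))[1, ]),
               c(TRUE, TRUE, FALSE))
  expect_equal(unname(call_significance(rbind(c(0.06, 0.08)))[1, ]),
               c(FALSE, FALSE))
  expect_true(all(call_significance(rbind(c(0, 0, 0)))))
  expect_error(call_significance(rbind(c(0.1, 0.2)), primary = 0.2,
                                 secondary = 0.1), "primary")
  # monotone: lowering any LFSR never removes a call
  set.seed(51)
  lf <- matrix(runif(60), 20, 3)
  sig <- call_significance(lf)
  lf2 <- lf * matrix(runif(60), 20, 3)
  sig2 <- call_significance(lf2)
  expect_true(all(sig2[sig]))
})

test_that("top-eQTL selection picks the minimum significant LFSR with deterministic ties", {
  tests <- data.frame(gene = rep(c("g1", "g2", "g3"), each = 4),
                      snp = paste0("s", 1:12), pos = 1:12)
  set.seed(52)
  lfsr <- matrix(runif(12 * 2, 0.2, 1), 12, 2)
  lfsr[1, 1] <- 0.01; lfsr[2, 1] <- 0.02   # g1: s1 beats s2 in ct1
  lfsr[5, 2] <- 0.03                        # g2: only s5 in ct2
  betas <- matrix(rnorm(24), 12, 2)
  sig <- call_significance(lfsr)
  top <- select_top(tests, lfsr, sig, betas)
  expect_equal(top$snp[top$gene == "g1" & top$cell_type == "ct1"], "s1")
  expect_equal(top$snp[top$gene == "g2" & top$cell_type == "ct2"], "s5")
  expect_false("g3" %in% top$gene)
  # exhaustive-scan oracle
  for (r in 1:2) for (gn in unique(tests$gene)) {
    rows <- which(tests$gene == gn & sig[, r])
    if (!length(rows)) next
    want <- rows[order(lfsr[rows, r], -abs(betas[rows, r]),
                       tests$pos[rows])[1]]
    got <- top$row[top$gene == gn &
                     top$cell_type == paste0("ct", r)]
    expect_equal(got, want)
  }
})

test_that("pairwise sharing applies the factor-0.5 same-sign rule", {
  # three top eQTLs significant in both cell types
  sig <- matrix(TRUE, 3, 2, dimnames = list(NULL, c("a", "b")))
  betas <- rbind(c(0.4, 0.3),     # ratio 0.75, same sign -> shared
                 c(0.4, 0.1),     # ratio 0.25 -> not shared
                 c(0.4, -0.4))    # opposite sign -> not shared
  top <- data.frame(gene = paste0("g", 1:3), snp = paste0("s", 1:3),
                    row = 1:3)
  M <- pairwise_sharing(top, sig, betas)
  expect_equal(M["a", "b"], 1 / 3)
  expect_equal(M, t(M))
  expect_equal(diag(M), c(a = 1, b = 1))
  # no eligible pairs -> NA with message
  sig0 <- cbind(c(TRUE, TRUE, TRUE), c(FALSE, FALSE, FALSE))
  colnames(sig0) <- c("a", "b")
  expect_message(M0 <- pairwise_sharing(top, sig0, betas), "no eligible")
  expect_true(is.na(M0["a", "b"]))
})

test_that("global/multi/unique classification uses the R - buffer cut and partitions", {
  sig38 <- function(s) c(rep(TRUE, s), rep(FALSE, 38 - s))
  expect_equal(classify_sharing(rbind(sig38(37))), "global")
  expect_equal(classify_sharing(rbind(sig38(36))), "global")
  expect_equal(classify_sharing(rbind(sig38(35))), "multi")
  expect_equal(classify_sharing(rbind(sig38(10))), "multi")
  expect_equal(classify_sharing(rbind(sig38(1))), "unique")
  expect_equal(classify_sharing(rbind(sig38(0))), "none")
  # interaction analysis: R = 33, global at 31
  sig33 <- c(rep(TRUE, 31), rep(FALSE, 2))
  expect_equal(classify_sharing(rbind(sig33)), "global")
  # every significant row gets exactly one label
  set.seed(53)
  S <- matrix(runif(300) < 0.4, 50, 6)
  lab <- classify_sharing(S)
  expect_equal(length(lab), 50L)
  expect_true(all(lab %in% c("global", "multi", "unique", "none")))
  expect_equal(sum(table(lab)), 50L)
  expect_error(classify_sharing(rbind(c(TRUE, FALSE))), "at least 3")
})

test_that("sign adjustment orients the majority direction positive and is idempotent", {
  sig <- matrix(TRUE, 3, 3)
  b <- rbind(c(-1, -2, 0.5),      # majority negative -> flipped
             c(1, 2, 3),          # all positive -> unchanged
             c(-0.7, 0, 0))
  sig[3, 2:3] <- FALSE            # single significant negative entry
  out <- sign_adjust(b, sig)
  expect_equal(out[1, ], c(1, 2, -0.5))
  expect_equal(out[2, ], c(1, 2, 3))
  expect_equal(out[3, ], c(0.7, 0, 0))
  expect_equal(sign_adjust(out, sig), out)
})

test_that("representative pruning follows the single/pair/cluster rules", {
  R <- 4
  mk_top <- function(betas, nsig) {
    n <- nrow(betas)
    sig <- t(sapply(nsig, function(s) c(rep(TRUE, s), rep(FALSE, R - s))))
    lfsr <- matrix(0.01, n, R)
    top <- data.frame(gene = rep("g1", n), snp = paste0("s", 1:n),
                      cell_type = "ct1", row = 1:n)
    list(top = top, sig = sig, lfsr = lfsr)
  }
  # single top eQTL: retained
  x <- mk_top(rbind(c(1, 1, 0, 0)), 2)
  expect_equal(nrow(prune_representatives(x$top, rbind(c(1, 1, 0, 0)),
                                          x$sig, x$lfsr)), 1L)
  # two identical effect vectors: keep the one significant in more cell types
  b2 <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0))
  x2 <- mk_top(b2, c(2, 3))
  out2 <- prune_representatives(x2$top, b2, x2$sig, x2$lfsr)
  expect_equal(out2$snp, "s2")
  # two distant vectors: both retained
  b3 <- rbind(c(2, 2, 0, 0), c(0, 0, 2, 2))
  x3 <- mk_top(b3, c(2, 2))
  expect_equal(nrow(prune_representatives(x3$top, b3, x3$sig, x3$lfsr)), 2L)
  # three mutually distant vectors: all retained
  b4 <- rbind(c(3, 0, 0, 0), c(0, 3, 0, 0), c(0, 0, 3, 0))
  x4 <- mk_top(b4, c(1, 1, 1))
  expect_equal(nrow(prune_representatives(x4$top, b4, x4$sig, x4$lfsr)), 3L)
  # two tight clusters of two: one representative each (the more significant)
  b5 <- rbind(c(2, 2, 0, 0), c(2.02, 2.02, 0, 0),
              c(0, 0, 2, 2), c(0, 0, 2.02, 2.02))
  x5 <- mk_top(b5, c(3, 2, 3, 2))
  out5 <- prune_representatives(x5$top, b5, x5$sig, x5$lfsr)
  expect_setequal(out5$snp, c("s1", "s3"))
})

test_that("heatmap matrix masks non-significant cells", {
  sig <- rbind(c(TRUE, FALSE, TRUE))
  b <- rbind(c(-2, 5, -1))
  top <- data.frame(gene = "g1", snp = "s1", row = 1)
  H <- effect_heatmap_matrix(top, b, sig)
  expect_equal(unname(H[1, ]), c(2, 0, 1))
})
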