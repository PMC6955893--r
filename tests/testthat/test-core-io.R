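test_that("community table validation enforces the count-table contract", {
  tab <- toy_2x2()
  expect_equal(unclass(tab)[1, ], c(t1 = 5L, t2 = 0L))

  # non-integer cells are rejected with the offending cell named
  f <- tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "t1\t5\t1", "t2\t3.7\t2"), f)
  expect_error(read_community_table(f), "3.7.*s1.*t2")

  # duplicate identifiers are rejected
  m <- matrix(1L, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(community_table(m), "duplicate sample ids")
  m2 <- matrix(1L, 2, 2, dimnames = list(c("a", "b"), c("x", "x")))
  expect_error(community_table(m2), "duplicate taxon ids")

  # empty samples are an error, empty taxa are dropped with a warning
  m3 <- matrix(c(0L, 0L, 1L, 2L), 2, 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(community_table(t(m3)), "all-zero sample")
  m4 <- matrix(c(1L, 2L, 0L, 0L), 2, 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  expect_warning(out <- community_table(m4), "all-zero taxa")
  expect_equal(colnames(out), "x")
  expect_error(community_table(matrix(-1L, 2, 2)), "non-negative")
})

test_that("count tables round-trip losslessly through TSV in both orientations", {
  tab <- random_table(n = 100, S = 50, depth = 400, seed = 42)
  for (taxa_rows in c(TRUE, FALSE)) {
    f <- tempfile(fileext = ".tsv")
    write_community_table(tab, f, taxa_as_rows = taxa_rows)
    back <- read_community_table(f, taxa_as_rows = taxa_rows, quiet = TRUE)
    expect_identical(unclass(back), unclass(tab))
  }
})

test_that("rarefaction conserves depth exactly and is reproducible", {
  tab <- random_table(n = 8, S = 40, depth = 500, seed = 3)
  r <- rarefy(tab, depth = 200, seed = 7, quiet = TRUE)
  expect_true(all(rowSums(r) == 200))
  full <- unclass(tab)[, colnames(r)]
  expect_true(all(unclass(r) <= full))
  r2 <- rarefy(tab, depth = 200, seed = 7, quiet = TRUE)
  expect_identical(unclass(r), unclass(r2))
  r3 <- rarefy(tab, depth = 200, seed = 8, quiet = TRUE)
  expect_false(identical(unclass(r), unclass(r3)))

  # per-sample substreams: a sample's draw ignores the other samples
  sub <- community_table(unclass(tab)[1:3, ], quiet = TRUE)
  rs <- rarefy(sub, depth = 200, seed = 7, quiet = TRUE)
  expect_identical(unclass(rs)[1, ], unclass(r)[1, colnames(rs)])

  expect_error(rarefy(tab, depth = 0), "positive")
  expect_error(rarefy(tab, depth = 501), "shallower.*s1")
  # depth equal to the total is the identity
  one <- community_table(matrix(c(10L, 0L, 5L), 1, 3,
                                dimnames = list("s", c("a", "b", "c"))),
                         quiet = TRUE)
  expect_equal(as.vector(unclass(rarefy(one, 15, quiet = TRUE))),
               c(10L, 5L))
})

test_that("rarefaction sampling is hypergeometric in distribution", {
  tab <- community_table(matrix(c(1000L, 1000L), 1, 2,
                                dimnames = list("s", c("a", "b"))),
                         quiet = TRUE)
  n_seed <- 200
  firsts <- vapply(seq_len(n_seed), function(s)
    unclass(rarefy(tab, 1000, seed = s, quiet = TRUE))[1, "a"], 0L)
  # hypergeometric mean 500, var n*K/N*(1-K/N)*(N-n)/(N-1)
  v <- 1000 * 0.5 * 0.5 * (1000 / 1999)
  se <- sqrt(v / n_seed)
  expect_lt(abs(mean(firsts) - 500), 3 * se)
})

test_that("rank aggregation sums counts and conserves the grand total", {
  tab <- community_table(matrix(c(3L, 4L, 2L, 1L, 0L, 5L), 2, 3,
                                dimnames = list(c("s1", "s2"),
                                                c("a1", "a2", "a3"))),
                         quiet = TRUE)
  tax <- data.frame(taxon_id = c("a1", "a2", "a3"),
                    genus = c("G1", "G1", "G2"),
                    stringsAsFactors = FALSE)
  agg <- aggregate_by_rank(tab, tax, "genus")
  # column-major layout: a1 = (3,4), a2 = (2,1), a3 = (0,5)
  expect_equal(unclass(agg)[, "G1"], c(s1 = 5L, s2 = 5L))
  expect_equal(unclass(agg)[, "G2"], c(s1 = 0L, s2 = 5L))
  expect_equal(sum(agg), sum(tab))

  # all distinct genera: identity up to relabelling
  tax2 <- data.frame(taxon_id = c("a1", "a2", "a3"),
                     genus = c("Gx", "Gy", "Gz"))
  agg2 <- aggregate_by_rank(tab, tax2, "genus")
  expect_equal(unname(unclass(agg2)), unname(unclass(tab)))

  # random table against a groupby-sum oracle
  big <- random_table(n = 10, S = 60, depth = 300, seed = 9)
  lin <- data.frame(taxon_id = colnames(big),
                    genus = paste0("G", sample(1:12, ncol(big),
                                               replace = TRUE)))
  agg3 <- aggregate_by_rank(big, lin, "genus")
  oracle <- t(rowsum(t(unclass(big)),
                     lin$genus[match(colnames(big), lin$taxon_id)]))
  expect_equal(unclass(agg3)[, colnames(oracle)], oracle)

  expect_error(aggregate_by_rank(tab, tax[1:2, ], "genus"), "missing")
  pooled <- aggregate_by_rank(tab, tax[1:2, ], "genus", missing = "pool")
  expect_true("Unassigned" %in% colnames(pooled))
  expect_equal(sum(pooled), sum(tab))
  expect_error(aggregate_by_rank(tab, tax, "family"), "not present")
})

test_that("metadata and taxonomy readers validate their inputs", {
  f <- tempfile(fileext = ".tsv")
  md <- data.frame(sample_id = c("s1", "s2", "s3"),
                   environment = c("a", "a", "b"), site = "S1",
                   x = 1:3, y = 0, EC = c(1, 2, 3), flat = 1)
  utils::write.table(md, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(got <- read_sample_metadata(f), "constant.*flat")
  expect_true("EC" %in% names(got) && !"flat" %in% names(got))
  expect_s3_class(got$environment, "factor")

  writeLines("sample_id\tenvironment\tsite\tx", f)
  expect_error(read_sample_metadata(f), "required columns.*y")

  writeLines(c("taxon_id\tlineage",
               "a1\tBacteria;Proteobacteria;Gamma",
               "a2\tBacteria"), f)
  tx <- read_taxonomy_table(f)
  expect_equal(tx$class, c("Gamma", "Unassigned"))
  expect_equal(tx$domain, c("Bacteria", "Bacteria"))
})
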