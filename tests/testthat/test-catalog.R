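test_that("DNF expansion reproduces small tables", {
  and_tt <- hkm_truth_table(hkm_and(1, 2))
  expect_equal(format(hkm_dnf(and_tt)), "x1 AND x2")
  maj <- hkm_truth_table(hkm_sum(1, 2, 3, t = 2))
  dnf <- hkm_dnf(maj)
  expect_equal(length(dnf$children), 4L)  # one minterm per true row
  expect_equal(hkm_truth_table(dnf, n = 3)$bits, maj$bits)
  x1 <- hkm_truth_table(hkm_var(1))
  expect_equal(format(hkm_dnf(x1)), "x1")
  const <- structure(list(n = 1L, bits = c(TRUE, TRUE)),
                     class = "hkm_truth_table")
  expect_error(hkm_dnf(const), "constant")
})

test_that("the catalog holds the expected classes at each size", {
  catalog <- hkm_catalog()
  # size 1: a variable and its negation
  expect_equal(sort(catalog$by_n[[1]]$string), sort(c("x1", "NOT x1")))
  # size 2 with AND/OR/NOT: {AND, OR} x {0, 1, 2} negations = 6 classes
  expect_equal(length(unique(catalog$by_n[[2]]$perm_class)), 6L)
  # majority-of-3 simplifies to the SUM form, not its 4-minterm DNF
  maj <- hkm_truth_table(hkm_sum(1, 2, 3, t = 2))
  expect_equal(format(hkm_simplify(maj, catalog)), "SUM(x1, x2, x3) >= 2")
  # XOR needs a repeated variable: absent
  xor2 <- structure(list(n = 2L, bits = c(FALSE, TRUE, TRUE, FALSE)),
                    class = "hkm_truth_table")
  expect_null(hkm_simplify(xor2, catalog))
  expect_equal(format(hkm_simplify(hkm_truth_table(hkm_and(1, 2)), catalog)),
               "x1 AND x2")
  expect_error(hkm_simplify(structure(list(n = 1L, bits = c(FALSE, FALSE)),
                                      class = "hkm_truth_table"), catalog),
               "constant")
})

test_that("catalog entries are sound: each formula reproduces its key", {
  catalog <- hkm_catalog()
  for (n in 1:4) {
    tb <- catalog$by_n[[n]]
    for (i in seq_len(nrow(tb))) {
      tt <- hkm_truth_table(tb$formula[[i]], n = n)
      expect_identical(paste(as.integer(tt$bits), collapse = ""), tb$key[i])
      expect_true(hkm_is_proper(tt))
      expect_true(hkm_is_admissible(tb$formula[[i]]))
      expect_equal(hkm_operator_count(tb$formula[[i]]), tb$ops[i])
    }
  }
})

test_that("catalog is complete and minimal against brute-force enumeration", {
  catalog <- hkm_catalog()
  for (n in 1:3) {
    oracle <- o_min_ops_by_table(n)
    tb <- catalog$by_n[[n]]
    expect_setequal(tb$key, names(oracle))
    expect_equal(tb$ops, as.integer(oracle[tb$key]))
  }
})

test_that("permuting variable labels maps catalog keys to equal-cost keys", {
  catalog <- hkm_catalog()
  for (n in 2:4) {
    tb <- catalog$by_n[[n]]
    ops_by_key <- stats::setNames(tb$ops, tb$key)
    r <- 0:(2^n - 1)
    # swap x1 and x2
    s <- bitwAnd(r, bitwNot(3L))
    s <- s + bitwShiftL(bitwAnd(r, 1L), 1L) + bitwShiftR(bitwAnd(r, 2L), 1L)
    for (i in seq_len(nrow(tb))) {
      bits <- as.integer(strsplit(tb$key[i], "")[[1]])
      swapped <- paste(bits[s + 1L], collapse = "")
      expect_true(swapped %in% tb$key)
      expect_equal(ops_by_key[[swapped]], tb$ops[i])
    }
  }
})

test_that("class counts stay within the constant formula bound", {
  catalog <- hkm_catalog()
  per_size <- vapply(catalog$by_n, function(tb) length(unique(tb$perm_class)),
                     integer(1))
  expect_equal(per_size[1], 2L)
  expect_true(all(per_size < 100))
  expect_lte(hkm_semantic_classes(catalog), 100L)
})

test_that("the catalog export round-trips through its JSON reader", {
  catalog <- hkm_catalog(hkm_constraints(max_vars = 2))
  path <- withr::local_tempfile(fileext = ".json")
  hkm_catalog_export(catalog, path)
  back <- hkm_catalog_import(path)
  expect_equal(nrow(back), sum(vapply(catalog$by_n, nrow, integer(1))))
  for (i in seq_len(nrow(back))) {
    tt <- hkm_truth_table(back$formula[[i]], n = back$n[i])
    expect_equal(paste(as.integer(tt$bits), collapse = ""), back$key[i])
  }
})
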