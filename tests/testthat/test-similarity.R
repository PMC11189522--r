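test_that("align_identity handles the closed-form cases", {
  r <- align_identity("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(r$identity, 1)
  expect_equal(r$aligned_columns, 10L)

  # equal length, one substitution: ungapped global alignment is optimal
  r <- align_identity("ACDEFGHIKL", "ACDEFGHIKV",
                      align_params(mode = "global"))
  expect_equal(r$identity, 0.9)
  expect_equal(r$aligned_columns, 10L)
})

test_that("align_identity is symmetric", {
  set.seed(41)
  for (k in 1:200) {
    mode <- if (k %% 2) "local" else "global"
    a <- random_protein(sample(8:40, 1))
    b <- random_protein(sample(8:40, 1))
    p <- align_params(mode = mode)
    expect_equal(align_identity(a, b, p), align_identity(b, a, p))
  }
})

test_that("a shared 12-mer in local mode matches the exhaustive DP oracle", {
  set.seed(7)
  core <- random_protein(12)
  a <- paste0(random_protein(14), core, random_protein(14))
  b <- paste0(random_protein(20), core, random_protein(8))
  r <- align_identity(a, b, align_params(mode = "local"))
  o <- oracle_align(a, b, "local")
  expect_equal(r$raw_score, o$score)
  nm <- round(r$identity * r$aligned_columns)
  expect_gte(nm, o$nm_min); expect_lte(nm, o$nm_max)
  expect_gte(r$aligned_columns, o$cols_min)
  expect_lte(r$aligned_columns, o$cols_max)
})

test_that("alignment parameter invariants are enforced", {
  expect_error(align_params(gap_open = 2, gap_extend = 5), "gap_extend")
  expect_error(align_identity("AC1D", "ACDE"), "outside")
})

test_that("NCBI-format matrices can be read and used for alignment", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# tiny identity-ish matrix",
               "   A  C  D",
               "A  4 -2 -2",
               "C -2  4 -2",
               "D -2 -2  4"), path)
  m <- read_score_matrix(path)
  expect_equal(dim(m), c(3, 3))
  expect_equal(m["A", "A"], 4L)
  r <- align_identity("ACD", "ACD",
                      align_params(substitution_matrix = m))
  expect_equal(r$raw_score, 12)
})

test_that("reduce_redundancy collapses identical and keeps unrelated sequences", {
  s <- seq_tbl(paste0("s", 1:5), rep("ACDEFGHIKLMNPQRSTVWY", 5))
  red <- reduce_redundancy(s, threshold = 0.8)
  expect_equal(nrow(red$representatives), 1)
  expect_true(all(red$membership$representative_id == "s1"))

  set.seed(5)
  u <- seq_tbl(paste0("u", 1:3),
               vapply(1:3, function(i) random_protein(60), ""))
  red <- reduce_redundancy(u, threshold = 0.8)
  expect_equal(nrow(red$representatives), 3)

  expect_error(reduce_redundancy(u[0, ]), "non-empty")
})

test_that("reduce_redundancy groups near-identical pairs and is oracle-consistent", {
  set.seed(11)
  a <- random_protein(12)
  av <- strsplit(a, "")[[1]]
  av[6] <- setdiff(c("A", "W"), av[6])[1]
  b <- paste(av, collapse = "")  # one substitution: identity 11/12
  c_ <- random_protein(40)
  s <- seq_tbl(c("A", "B", "C"), c(a, b, c_))
  red <- reduce_redundancy(s, threshold = 0.8)
  expect_setequal(red$representatives$id, c("A", "C"))
  m <- red$membership
  expect_equal(m$representative_id[m$id == "B"], "A")
  expect_gte(m$identity[m$id == "B"], 11 / 12 - 1e-9)
  # pairwise identities against the DP oracle (global mode: equal lengths)
  r_ab <- align_identity(a, b, align_params(mode = "global"))
  expect_true(oracle_consistent(r_ab, a, b, "global"))
})

test_that("at threshold 1 every distinct sequence is its own representative", {
  set.seed(13)
  s <- seq_tbl(paste0("s", 1:6),
               c(vapply(1:5, function(i) random_protein(30), ""),
                 "ACDEFGHIKL"))
  red <- reduce_redundancy(s, threshold = 1)
  expect_equal(nrow(red$representatives), 6)
  expect_equal(red$membership$representative_id, red$membership$id)
})

test_that("redundancy postconditions hold on a synthetic family corpus", {
  co <- generate_families(3, 5, length = 80, p_sub = 0.05, seed = 21)
  red <- reduce_redundancy(co, threshold = 0.8)
  # every member at or above threshold to its representative
  nonrep <- red$membership[red$membership$id !=
                             red$membership$representative_id, ]
  expect_true(all(nonrep$identity >= 0.8))
  # representatives mutually below threshold
  reps <- red$representatives
  if (nrow(reps) >= 2) {
    for (i in 1:(nrow(reps) - 1)) {
      for (j in (i + 1):nrow(reps)) {
        r <- align_identity(reps$residues[i], reps$residues[j],
                            align_params(mode = "global"))
        expect_lt(r$identity, 0.8)
      }
    }
  }
})
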