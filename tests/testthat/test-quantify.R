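test_that("coverage and relative abundance follow their defining equations", {
  expect_equal(compute_coverage(1000, 500), 2.0)
  expect_equal(compute_coverage(0, 40000), 0.0)
  expect_equal(compute_coverage(250, 1000), 0.25)
  expect_error(compute_coverage(10, 0), "positive")
  expect_error(compute_coverage(-1, 10), "non-negative")

  expect_equal(as.numeric(compute_relative_abundance(c(A = 2, B = 2))),
               c(0.5, 0.5))
  expect_equal(as.numeric(compute_relative_abundance(c(A = 3, B = 1))),
               c(0.75, 0.25))
  zero <- compute_relative_abundance(c(A = 0, B = 0))
  expect_equal(as.numeric(zero), c(0, 0))
  expect_true(attr(zero, "degenerate"))
  expect_error(compute_relative_abundance(c(-1, 1)), "non-negative")
})

test_that("relative abundance normalises on randomized coverage vectors", {
  withr::with_seed(31, {
    for (i in 1:1000) {
      cov <- runif(sample(1:10, 1), 0, 50)
      ra <- compute_relative_abundance(cov)
      expect_lt(abs(sum(ra) - 1), 1e-9)
      expect_equal(order(ra), order(cov))
    }
  })
})

test_that("unique assignment seeds the abundance table", {
  refs <- reference_set(c(A = random_dna(100), B = random_dna(100)))
  asn <- worked_example_assignments()[1:4, ]  # 3 unique A + 1 unique B
  ab <- assign_unique(asn, refs)
  expect_equal(ab$mbp, c(60, 20))
  expect_equal(ab$coverage, c(0.6, 0.2))
  expect_equal(ab$ra, c(0.75, 0.25))
  expect_equal(unique(ab$stage), "after_unique")

  # no unique pairs: degenerate all-zero table
  none <- assign_unique(asn[0, ], refs)
  expect_equal(none$ra, c(0, 0))
})

test_that("zero-unique tie pre-pass sends bases to supported members only", {
  refs <- reference_set(c(A = random_dna(100), B = random_dna(100),
                          C = random_dna(100)))
  stage1 <- tibble::tibble(ref_id = c("A", "B", "C"),
                           mbp = c(60, 30, 0),
                           coverage = c(0.6, 0.3, 0),
                           ra = c(2 / 3, 1 / 3, 0),
                           stage = "after_unique")
  groups <- tibble::tibble(key = "A\tB\tC",
                           members = list(c("A", "B", "C")),
                           mapped_bases = 90, n_pairs = 3L)
  res <- resolve_zero_unique_ties(stage1, groups, refs)
  expect_equal(res$abundance$mbp, c(120, 60, 0))
  expect_equal(nrow(res$unresolved), 0L)

  # two-member case: everything to the supported reference
  stage1b <- tibble::tibble(ref_id = c("A", "B", "C"),
                            mbp = c(60, 0, 0), coverage = c(0.6, 0, 0),
                            ra = c(1, 0, 0), stage = "after_unique")
  gb <- tibble::tibble(key = "A\tB", members = list(c("A", "B")),
                       mapped_bases = 100, n_pairs = 5L)
  resb <- resolve_zero_unique_ties(stage1b, gb, refs)
  expect_equal(resb$abundance$mbp, c(160, 0, 0))

  # all members supported: group passes through unresolved
  gc_ <- tibble::tibble(key = "A\tB", members = list(c("A", "B")),
                        mapped_bases = 50, n_pairs = 2L)
  resc <- resolve_zero_unique_ties(stage1, gc_, refs)
  expect_equal(resc$abundance$mbp, c(60, 30, 0))
  expect_equal(nrow(resc$unresolved), 1L)
})

test_that("remaining ties split proportionally, equal-split fallback is flagged", {
  refs <- reference_set(c(A = random_dna(100), B = random_dna(100)))
  tab <- tibble::tibble(ref_id = c("A", "B"), mbp = c(60, 20),
                        coverage = c(0.6, 0.2), ra = c(0.75, 0.25),
                        stage = "after_zero_unique_ties")
  g <- tibble::tibble(key = "A\tB", members = list(c("A", "B")),
                      mapped_bases = 80, n_pairs = 4L)
  fin <- resolve_ties(tab, g, refs)
  expect_equal(fin$mbp, c(120, 40))
  expect_equal(fin$ra, c(0.75, 0.25))
  expect_length(attr(fin, "flagged_groups"), 0L)

  zero <- tibble::tibble(ref_id = c("A", "B"), mbp = c(0, 0),
                         coverage = c(0, 0), ra = c(0, 0),
                         stage = "after_zero_unique_ties")
  fin0 <- resolve_ties(zero, g, refs)
  expect_equal(fin0$mbp, c(40, 40))
  expect_equal(attr(fin0, "flagged_groups"), "A,B")
})

test_that("the two-reference worked example yields RA 0.75 / 0.25 exactly", {
  refs <- reference_set(c(A = random_dna(100), B = random_dna(100)))
  q <- quantify(worked_example_assignments(), refs)
  expect_equal(q$abundance$mbp, c(120, 40))
  expect_equal(q$abundance$ra, c(0.75, 0.25))
  expect_equal(q$report$n_unique, 4L)
  expect_equal(q$report$n_tied, 4L)
})

test_that("quantify handles the degenerate and single-reference corners", {
  refs <- reference_set(c(A = random_dna(100), B = random_dna(100)))
  only_a <- worked_example_assignments()[1:3, ]
  q <- quantify(only_a, refs)
  expect_equal(q$abundance$ra, c(1, 0))

  none <- worked_example_assignments()[0, ]
  q0 <- quantify(none, refs)
  expect_equal(q0$abundance$ra, c(0, 0))
  expect_true(q0$report$degenerate)
  expect_error(quantify(only_a, refs[0, ]), "at least one")
})

test_that("base conservation and normalization hold across random instances", {
  withr::with_seed(32, {
    for (i in 1:50) {
      inst <- random_instance()
      refs <- reference_set(setNames(
        vapply(inst$g, random_dna, ""), inst$ref_ids))
      q <- pkg_quantify_instance(inst$pair_sets, inst$bases, refs)
      for (st in unique(q$stages$stage)) {
        tab <- q$stages[q$stages$stage == st, ]
        if (st == "after_unique") {
          uniq_bases <- sum(inst$bases[lengths(inst$pair_sets) == 1])
          expect_equal(sum(tab$mbp), uniq_bases, tolerance = 1e-6)
        }
        if (sum(tab$coverage) > 0)
          expect_lt(abs(sum(tab$ra) - 1), 1e-9)
      }
      expect_equal(sum(q$abundance$mbp), sum(inst$bases),
                   tolerance = 1e-6)
    }
  })
})

test_that("ties spanning all equal-length references leave RA at the unique-stage value", {
  withr::with_seed(33, {
    for (i in 1:20) {
      n_refs <- sample(2:4, 1)
      ref_ids <- LETTERS[seq_len(n_refs)]
      g <- rep(1000L, n_refs)
      n_u <- sample(2:10, 1)
      sets <- c(lapply(sample(ref_ids, n_u, replace = TRUE), identity),
                replicate(sample(1:8, 1), ref_ids, simplify = FALSE))
      bases <- sample(50:400, length(sets), replace = TRUE)
      refs <- reference_set(setNames(vapply(g, random_dna, ""), ref_ids))
      q <- pkg_quantify_instance(sets, bases, refs)
      st1 <- q$stages[q$stages$stage == "after_unique", ]
      expect_equal(q$abundance$ra, st1$ra, tolerance = 1e-12)
    }
  })
})

test_that("adding a unique pair for a reference never decreases its final RA", {
  withr::with_seed(34, {
    for (i in 1:30) {
      inst <- random_instance(n_refs = sample(2:3, 1))
      refs <- reference_set(setNames(
        vapply(inst$g, random_dna, ""), inst$ref_ids))
      r <- sample(inst$ref_ids, 1)
      q1 <- pkg_quantify_instance(inst$pair_sets, inst$bases, refs)
      q2 <- pkg_quantify_instance(c(inst$pair_sets, list(r)),
                                  c(inst$bases, 200), refs)
      ra1 <- q1$abundance$ra[q1$abundance$ref_id == r]
      ra2 <- q2$abundance$ra[q2$abundance$ref_id == r]
      expect_gte(ra2, ra1 - 1e-12)
    }
  })
})

test_that("the minimum-RA noise threshold zeroes and renormalises", {
  refs <- reference_set(c(A = random_dna(100), B = random_dna(100)))
  asn <- worked_example_assignments()
  q <- quantify(asn, refs, min_ra = 0.3)
  expect_equal(q$abundance$ra, c(1, 0))
  expect_true(q$report$thresholded)
})

test_that("tidy, glance and autoplot expose the result", {
  refs <- reference_set(c(A = random_dna(100), B = random_dna(100)))
  q <- quantify(worked_example_assignments(), refs)
  td <- tidy(q)
  expect_equal(td$ra, c(0.75, 0.25))
  expect_equal(nrow(tidy(q, stage = c("after_unique", "final"))), 4L)
  gl <- glance(q)
  expect_equal(gl$n_pairs, 8L)
  expect_s3_class(autoplot(q), "ggplot")
})
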