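test_that("HMMER3 writer/reader round-trips a profile exactly", {
  set.seed(41)
  rows <- replicate(15, random_dist(0.4), simplify = FALSE)
  hmm <- profile_from_rows("rt_model", "ab_initio", rows)
  path <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3_profile(hmm, path)
  back <- read_hmmer3_profile(path)
  expect_identical(back$model_id, "rt_model")
  expect_identical(back$length, 15L)
  expect_lt(max(abs(back$emissions - hmm$emissions)), 1e-9)
  expect_identical(back$residue_map, hmm$residue_map)
})

test_that("real hmmbuild output parses with sane emissions", {
  path <- system.file("extdata", "toy.hmm", package = "pathmm")
  hmm <- read_hmmer3_profile(path)
  expect_identical(hmm$model_id, "toy")
  expect_identical(hmm$length, 10L)
  expect_equal(unname(rowSums(hmm$emissions)), rep(1, 10), tolerance = 1e-9)
  consensus <- paste(amino_acids()[max.col(hmm$emissions)], collapse = "")
  expect_identical(consensus, "MKVLAARTGE")
})

test_that("stored negative-log emissions convert as exp(-x)", {
  # one state: residue A stored as 0.0 (prob 1), everything else "*"
  lines <- c("HMMER3/f [test]", "NAME  one", "LENG  1", "ALPH  amino",
             paste("HMM ", paste(amino_acids(), collapse = " ")),
             "  m->m m->i m->d i->m i->i d->m d->d",
             paste("  1  0.0", paste(rep("*", 19), collapse = " ")),
             "//")
  hmm <- read_hmmer3_profile(lines)
  expect_equal(unname(hmm$emissions[1, "A"]), 1, tolerance = 1e-6)
  expect_true(all(hmm$emissions[1, -1] <= 2e-9))
  # all-ln(20) profile is uniform
  lines2 <- c("HMMER3/f [test]", "NAME  u", "LENG  2", "ALPH  amino",
              paste("HMM ", paste(amino_acids(), collapse = " ")),
              "  m->m m->i m->d i->m i->i d->m d->d",
              paste("  1 ", paste(rep(sprintf("%.8f", log(20)), 20),
                                  collapse = " ")),
              paste("  2 ", paste(rep(sprintf("%.8f", log(20)), 20),
                                  collapse = " ")),
              "//")
  hmm2 <- read_hmmer3_profile(lines2)
  expect_equal(unname(hmm2$emissions), matrix(0.05, 2, 20),
               tolerance = 1e-7)
})

test_that("malformed profiles fail with informative errors", {
  good <- c("HMMER3/f [t]", "NAME  x", "LENG  2", "ALPH  amino",
            paste("HMM ", paste(amino_acids(), collapse = " ")),
            "  m->m m->i m->d i->m i->i d->m d->d",
            paste("  1 ", paste(rep("2.9957", 20), collapse = " ")),
            paste("  2 ", paste(rep("2.9957", 20), collapse = " ")),
            "//")
  bad_header <- good
  bad_header[1] <- "HMMER2.0"
  expect_error(read_hmmer3_profile(bad_header), "line 1")
  short <- good[-8]  # one emission line missing
  expect_error(read_hmmer3_profile(short), "LENG")
  bad_field <- good
  bad_field[7] <- paste("  1 ", paste(rep("2.9957", 19), collapse = " "),
                        " oops")
  expect_error(read_hmmer3_profile(bad_field), "line 7")
  dna <- good
  dna[4] <- "ALPH  DNA"
  expect_error(read_hmmer3_profile(dna), "amino")
})

test_that("kl_divergence matches direct summation and is non-negative", {
  u <- uniform_dist()
  expect_identical(kl_divergence(u, u), 0)
  p <- point_dist("W", 1)
  expect_equal(kl_divergence(p, u), log(20), tolerance = 1e-9)
  half <- stats::setNames(c(0.5, 0.5, rep(0, 18)), amino_acids())
  expect_equal(kl_divergence(half, u), log(10), tolerance = 1e-9)
  set.seed(99)
  for (i in 1:50) {
    d <- random_dist(runif(1, 0.1, 4))
    q <- random_dist(runif(1, 0.5, 4))
    q <- (q + 0.01) / sum(q + 0.01)   # strictly positive background
    expect_equal(kl_divergence(d, q), kl_brute(d, q), tolerance = 1e-12)
    expect_gte(kl_divergence(d, q), 0)
  }
  # zero iff equal
  expect_lt(kl_divergence(aa_background(), aa_background()), 1e-12)
})

test_that("candidates_for_residue always includes ab initio plus coverers", {
  set <- tiny_set()
  # residue 2 of protA: outside the domain -> only ab initio
  c1 <- candidates_in_set(set, "protA", 2)
  expect_length(c1, 1)
  expect_identical(c1[[1]]$model$source, "ab_initio")
  # residue 5 of protA: inside dom1 -> two candidates, domain state 2
  c2 <- candidates_in_set(set, "protA", 5)
  expect_length(c2, 2)
  expect_identical(c2[[2]]$model$model_id, "dom1")
  expect_identical(c2[[2]]$state, 2L)
  # same domain on protB starts at residue 2: residue 2 -> state 1
  c3 <- candidates_in_set(set, "protB", 2)
  expect_identical(c3[[2]]$state, 1L)
  # uncovered residue errors
  expect_error(candidates_in_set(set, "protA", 40), "not covered")
})

test_that("nested annotations yield one candidate per covering model", {
  set <- tiny_set()
  extra <- profile_from_rows("sf1", "superfamily",
                             replicate(8, uniform_dist(),
                                       simplify = FALSE))
  ann <- rbind(set$annotations,
               data.frame(protein_id = "protA", model_id = "sf1",
                          source = "superfamily", start = 3L, end = 10L,
                          model_start = 1L, stringsAsFactors = FALSE))
  set2 <- profile_set(set$ab_initio,
                      c(set$domains, list(sf1 = extra)), ann)
  expect_length(candidates_in_set(set2, "protA", 5), 3)
})

test_that("model selection maximizes positional KL with fixed tie-breaks", {
  u <- uniform_dist()
  cand_point <- list(model = profile_from_rows("p", "ab_initio",
                                               list(point_dist("A", 1))),
                     state = 1L)
  cand_unif <- list(model = profile_from_rows("q", "ab_initio",
                                              list(uniform_dist())),
                    state = 1L)
  expect_identical(
    select_informative_model(list(cand_unif, cand_point), u)$model$model_id,
    "p")
  expect_identical(
    select_informative_model(list(cand_point), u)$model$model_id, "p")
  expect_error(select_informative_model(list(), u), "no candidate")
  # identical emissions: pfam_a wins over ab_initio regardless of order
  rows <- list(random_dist(0.5))
  a <- list(model = profile_from_rows("m_ab", "ab_initio", rows), state = 1L)
  b <- list(model = profile_from_rows("m_pf", "pfam_a", rows), state = 1L)
  expect_identical(select_informative_model(list(a, b), u)$model$model_id,
                   "m_pf")
  expect_identical(select_informative_model(list(b, a), u)$model$model_id,
                   "m_pf")
})

test_that("model selection is invariant under candidate permutations", {
  set.seed(7)
  u <- uniform_dist()
  cands <- lapply(1:5, function(i) {
    list(model = profile_from_rows(paste0("m", i), "pfam_b",
                                   list(random_dist(0.6))), state = 1L)
  })
  ref <- select_informative_model(cands, u)$model$model_id
  for (i in 1:10) {
    perm <- sample(cands)
    expect_identical(select_informative_model(perm, u)$model$model_id, ref)
  }
})
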