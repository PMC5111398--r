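idx_small <- build_index(small_library$library)

test_that("exact substrings map uniquely with zero mismatches", {
  lib <- small_library$library
  for (i in c(1L, 3L)) {
    read <- substr(lib$sequence[i], 501, 600)
    hit <- map_read(read, idx_small)
    expect_equal(hit$status, "unique")
    expect_equal(hit$reference_id, lib$species_id[i])
    expect_equal(hit$position, 500L)
    expect_equal(hit$mismatches, 0L)
    expect_equal(hit$strand, "+")
  }
})

test_that("the mismatch budget is floor(read_length * rate), strictly", {
  read <- substr(small_library$library$sequence[2], 101, 200)
  expect_equal(map_read(mutate_read(read, 37), idx_small)$mismatches, 1L)
  expect_equal(map_read(mutate_read(read, 37), idx_small)$status, "unique")
  # two mismatches exceed floor(100 * 0.01) = 1 everywhere
  expect_equal(map_read(mutate_read(read, c(37, 71)), idx_small)$status,
               "unmapped")
})

test_that("reads spanning the circular origin map at the wrap position", {
  lib <- small_library$library
  L <- lib$achieved_length[1]
  read <- circular_window(lib$sequence[1], L - 49L, 100)
  hit <- map_read(read, idx_small)
  expect_equal(hit$status, "unique")
  expect_equal(hit$position, L - 50L)
  expect_equal(hit$mismatches, 0L)
})

test_that("minus-strand reads keep status, reference and position", {
  lib <- small_library$library
  reads <- draw_reads(lib$sequence[4], 50, seed = 8)
  for (r in reads[1:10]) {
    h1 <- map_read(r, idx_small)
    h2 <- map_read(revcomp_dna(r), idx_small)
    expect_equal(h2$status, h1$status)
    expect_equal(h2$reference_id, h1$reference_id)
    expect_equal(h2$position, h1$position)
    expect_equal(h2$mismatches, h1$mismatches)
  }
})

test_that("identical references yield multi_reference, never unique", {
  twin <- data.frame(species_id = c("t1", "t2"),
                     sequence = rep(tiny_refs$sequence[2], 2),
                     stringsAsFactors = FALSE)
  idx <- build_index(twin)
  read <- substr(twin$sequence[1], 11, 110)
  expect_equal(map_read(read, idx)$status, "multi_reference")
  mr <- map_reads(read, idx)
  expect_true(all(unlist(mr$depth) == 0))  # multi hits leave depth untouched
})

test_that("all-N reads are unmapped (N is a mismatch everywhere)", {
  expect_equal(map_read(strrep("N", 100), idx_small)$status, "unmapped")
})

test_that("depth accounting conserves read length per unique assignment", {
  lib <- small_library$library
  reads <- c(draw_reads(lib$sequence[1], 40, seed = 2),
             draw_reads(lib$sequence[2], 25, seed = 3))
  mr <- map_reads(reads, idx_small)
  uq <- mr$assignments[mr$assignments$status == "unique", ]
  for (s in lib$species_id)
    expect_equal(sum(mr$depth[[s]]), 100 * sum(uq$reference_id == s))
  expect_equal(nrow(mr$assignments), length(reads))  # order/count preserved
})

test_that("empty read sets give empty assignments and all-zero depth", {
  mr <- map_reads(character(), idx_small)
  expect_equal(nrow(mr$assignments), 0L)
  expect_true(all(vapply(mr$depth, sum, 0) == 0))
  expect_equal(lengths(mr$depth),
               setNames(small_library$library$achieved_length,
                        small_library$library$species_id))
})

test_that("raising the mismatch budget never turns unique into unmapped", {
  lib <- small_library$library
  reads <- draw_reads(lib$sequence[3], 30, seed = 5)
  reads <- vapply(seq_along(reads),
                  function(i) mutate_read(reads[i], (i %% 100) + 1L), "")
  strict <- build_index(lib, max_mismatch_rate = 0.01)
  loose <- build_index(lib, max_mismatch_rate = 0.03)
  s1 <- vapply(reads, function(r) map_read(r, strict)$status, "")
  s2 <- vapply(reads, function(r) map_read(r, loose)$status, "")
  expect_false(any(s1 == "unique" & s2 == "unmapped"))
})

test_that("indexed mapper agrees with the exhaustive-scan oracle", {
  lib <- small_library$library
  set <- character(0)
  for (i in seq_len(nrow(lib)))
    set <- c(set, draw_reads(lib$sequence[i], 80, seed = 60 + i))
  with_seed(99, {
    # perturb: 0, 1 or 2 mismatches; some unmappable random reads
    k <- sample(0:2, length(set), replace = TRUE)
    for (j in which(k > 0))
      set[j] <- mutate_read(set[j], sample.int(100, k[j]))
    set <- c(set, vapply(1:40, function(i) random_dna(100), ""))
  })
  fast <- map_reads(set, idx_small)$assignments
  for (j in seq_along(set)) {
    oracle <- brute_force_map(set[j], lib)
    expect_equal(fast$status[j], oracle$status, label = paste("read", j))
    if (oracle$status == "unique") {
      expect_equal(fast$reference_id[j], oracle$reference_id)
      expect_equal(fast$position[j], oracle$position)
      expect_equal(fast$strand[j], oracle$strand)
      expect_equal(fast$mismatches[j], oracle$mismatches)
    }
  }
})

test_that("both mapping routes agree with Biostrings mismatch counting", {
  skip_if_not_installed("Biostrings")
  lib <- small_library$library
  reads <- draw_reads(lib$sequence[2], 20, seed = 77)
  reads[1:10] <- vapply(1:10, function(i) mutate_read(reads[i], i * 7L), "")
  ext <- Biostrings::DNAStringSet(paste0(lib$sequence,
                                         substr(lib$sequence, 1, 99)))
  for (r in reads) {
    hit <- map_read(r, idx_small)
    best_bs <- min(vapply(seq_len(nrow(lib)), function(i) {
      min(c(Biostrings::neditStartingAt(Biostrings::DNAString(r), ext[[i]],
                                        starting.at = seq_len(nchar(lib$sequence[i]))),
            Biostrings::neditStartingAt(
              Biostrings::reverseComplement(Biostrings::DNAString(r)),
              ext[[i]],
              starting.at = seq_len(nchar(lib$sequence[i])))))
    }, 0))
    if (hit$status == "unique") expect_equal(hit$mismatches, best_bs)
    else if (hit$status == "unmapped") expect_gt(best_bs, 1)
  }
})
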