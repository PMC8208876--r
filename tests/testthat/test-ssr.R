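test_that("tandem repeat candidates are maximal, left-anchored, primitive", {
  r <- find_tandem_repeats("AAATTTTTTTTTTTAAA")
  tr <- r[r$unit == "T", ]
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$copy_number, 11L)
  expect_equal(c(tr$start, tr$end), c(4L, 14L))

  r <- find_tandem_repeats("ACACACACAC")
  expect_equal(r$unit, "AC")
  expect_equal(r$copy_number, 5L)

  # N terminates a run
  r <- find_tandem_repeats("TTTTTNTTTTT")
  expect_equal(r$copy_number, c(5L, 5L))
  expect_equal(r$start, c(1L, 7L))

  # trailing partial copy is recorded but not counted
  r <- find_tandem_repeats("GATCGATCGAT")
  g <- r[r$unit == "GATC", ]
  expect_equal(g$copy_number, 2L)
  expect_equal(g$trailing_partial_length, 3L)

  expect_error(find_tandem_repeats(""), "empty")
})

test_that("three-tier classification follows unit length and copy number", {
  # implied minimum copies for normal SSRs at the 10 bp threshold
  expect_equal(classify_ssr(1, 9), NA_character_)
  expect_equal(classify_ssr(1, 10), "normal")
  expect_equal(classify_ssr(2, 4), NA_character_)
  expect_equal(classify_ssr(2, 5), "normal")
  expect_equal(classify_ssr(3, 3), NA_character_)
  expect_equal(classify_ssr(3, 4), "normal")
  expect_equal(classify_ssr(4, 3), "normal")
  # penta/hexa at exactly 2 copies are potential, at 3+ normal
  expect_equal(classify_ssr(5, 2), "potential")
  expect_equal(classify_ssr(5, 3), "normal")
  expect_equal(classify_ssr(6, 2), "potential")
  expect_equal(classify_ssr(6, 3), "normal")
  # extended units need only 2 copies
  expect_equal(classify_ssr(7, 2), "extended")
  expect_equal(classify_ssr(10, 2), "extended")
  expect_equal(classify_ssr(4, 2), NA_character_)  # 8 bp < threshold
})

test_that("worked catalog examples classify as printed", {
  # homopolymer x10 reaches the threshold
  expect_equal(classify_ssr(1, 10), "normal")
  # AAATAT at 2 copies potential, at 3 copies normal (18 bp)
  expect_equal(classify_ssr(6, 2:3), c("potential", "normal"))
  # 7 bp unit at 2 copies is an extended heptaSSR
  cat1 <- find_ssrs(paste0("GGC", strrep("AATTATA", 2), "GGC"))
  expect_equal(cat1$category, "extended")
  expect_equal(cat1$ssr_type, "hepta")
  expect_equal(cat1$copy_number, 2L)
})

test_that("scanning a pure repeat yields a single left-anchored record", {
  cat1 <- find_ssrs("ACGTACGTACGT")
  expect_equal(nrow(cat1), 1L)
  expect_equal(cat1$unit, "ACGT")
  expect_equal(cat1$category, "normal")
  expect_equal(cat1$ssr_type, "tetra")
  expect_equal(c(cat1$start, cat1$end), c(1L, 12L))
  expect_equal(cat1$ssr_id, "Te0000001")
})

test_that("planted SSRs are recovered exactly, with catalog invariants", {
  g <- generate_genome(6000, 0.307, seed = 21)
  specs <- data.frame(
    unit = c("C", "AT", "ATT", "ATTA", "AAATG", "AAATAT", "AATTATA"),
    copy_number = c(11L, 7L, 4L, 3L, 2L, 3L, 2L))
  pl <- plant_ssrs(g, specs, seed = 8)
  cat1 <- find_ssrs(pl$genome)
  expect_equal(nrow(cat1), nrow(specs))
  cols <- c("unit", "copy_number", "start", "end", "category", "ssr_type")
  expect_equal(as.data.frame(cat1)[cols], as.data.frame(pl$manifest)[cols])
  # span identity on every record
  expect_equal(cat1$end - cat1$start + 1L,
               nchar(cat1$unit) * cat1$copy_number)
  # ids: per-type prefixes in start order
  expect_match(cat1$ssr_id[cat1$ssr_type == "mono"], "^M\\d{7}$")
  expect_match(cat1$ssr_id[cat1$ssr_type == "hepta"], "^cHp\\d{7}$")
  # determinism: byte-identical rescan
  expect_identical(find_ssrs(pl$genome), cat1)
})

test_that("scanner equals the brute-force enumerator on random sequences", {
  set.seed(99)
  for (i in 1:25) {
    # low-complexity alphabet mix makes repeats plentiful
    n <- sample(200:800, 1)
    s <- paste(sample(c("A", "T", "C", "G", "N"), n, replace = TRUE,
                      prob = c(.4, .4, .08, .08, .04)), collapse = "")
    mine <- find_tandem_repeats(s)
    oracle <- bf_tandem_repeats(s)
    expect_identical(mine[c("unit", "copy_number", "start", "end")],
                     oracle[c("unit", "copy_number", "start", "end")],
                     info = paste("seq", i))
  }
})

test_that("raising the length threshold never adds normal SSRs", {
  set.seed(5)
  for (i in 1:10) {
    s <- paste(sample(c("A", "T", "G", "C"), 2000, replace = TRUE,
                      prob = c(.4, .4, .1, .1)), collapse = "")
    counts <- vapply(c(10L, 12L, 14L, 16L), function(th) {
      cfg <- ssr_config(min_total_length_normal = th)
      sum(find_ssrs(s, cfg)$category == "normal")
    }, 0L)
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("count_by_type and max_ssr_length summarize the catalog", {
  g <- generate_genome(6000, 0.307, seed = 31)
  specs <- data.frame(unit = c("T", "T", "GA", "AAATAT", "AATTATA"),
                      copy_number = c(10L, 12L, 5L, 3L, 2L))
  pl <- plant_ssrs(g, specs, seed = 4)
  cat1 <- find_ssrs(pl$genome)
  tab <- count_by_type(cat1)
  expect_equal(tab$normal_extended[tab$ssr_type == "mono"], 2L)
  expect_equal(tab$normal_extended[tab$ssr_type == "di"], 1L)
  expect_equal(tab$normal_extended[tab$ssr_type == "hexa"], 1L)
  expect_equal(tab$normal_extended[tab$ssr_type == "hepta"], 1L)
  expect_equal(sum(tab$normal_extended) + sum(tab$potential), nrow(cat1))
  expect_equal(attr(tab, "subtotals"),
               c(normal_extended = 5L, potential = 0L))
  expect_equal(max_ssr_length(cat1), 18L)

  empty <- cat1[0, ]
  tab0 <- count_by_type(empty)
  expect_true(all(tab0$normal_extended == 0L) && all(tab0$potential == 0L))
  expect_error(max_ssr_length(empty), "no normal")
})
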