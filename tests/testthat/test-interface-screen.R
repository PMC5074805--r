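# Interface hydrophobicity counting and family-alignment screening.

test_that("interface counts match manual position lookups", {
  # parent hairpin: hydrophobic at 10 (L), 21 (I), 28 (V) only
  r <- hydrophobic_interface_count(rps20hhta_unit())
  expect_identical(r$hydrophobic_count, 3L)
  expect_identical(r$hydrophobic_positions$index, c(10L, 21L, 28L))
  expect_identical(r$hydrophobic_positions$residue, c("L", "I", "V"))
  # M2 repeat unit gains L at position 7
  m2_unit <- "IKTLSKLAVLLAQEGKAEEAIKYMRKAVSLDPNN"
  r2 <- hydrophobic_interface_count(m2_unit)
  expect_identical(r2$hydrophobic_count, 4L)
  expect_identical(r2$hydrophobic_positions$index, c(7L, 10L, 21L, 28L))
  # poly-glycine has none
  expect_identical(hydrophobic_interface_count(
    strrep("G", 34))$hydrophobic_count, 0L)
})

test_that("interface definition and fragment validation are enforced", {
  expect_error(hydrophobic_interface_count("SHORT"),
               class = "tpr_shape_error")
  expect_error(interface_definition(positions = c(3, 40)),
               class = "tpr_value_error")
  expect_error(interface_definition(hydrophobic_set = c("A", "W")),
               class = "tpr_value_error")
  expect_warning(
    r <- hydrophobic_interface_count(paste0("XX", strrep("A", 32))),
    "non-standard")
  expect_identical(r$hydrophobic_count, 5L)  # all interface positions are A
})

# Build a family alignment with a gapped reference row and planted
# hydrophobic-interface fragments with known ids.
make_family_fixture <- function(n_rich = 10L, n_poor = 15L, n_gappy = 3L,
                                seed = 51) {
  set.seed(seed)
  ref_frag <- rps20hhta_unit()
  polar <- c("S", "T", "N", "Q", "E", "K", "D", "R", "G")
  mk_frag <- function(n_hydro) {
    chars <- sample(polar, 34, replace = TRUE)
    pos <- interface_definition()$positions
    hyd <- sample(interface_definition()$hydrophobic_set, 34, replace = TRUE)
    take <- sample(pos, n_hydro)
    chars[take] <- hyd[take]
    paste(chars, collapse = "")
  }
  pad <- function(s) paste0("--", substr(s, 1, 17), "", substr(s, 18, 34),
                            "---")
  rows <- c(setNames(paste0("--", substr(ref_frag, 1, 17),
                            substr(ref_frag, 18, 34), "---"), "REF"))
  for (i in seq_len(n_rich)) {
    rows[sprintf("rich%02d", i)] <- pad(mk_frag(sample(3:5, 1)))
  }
  for (i in seq_len(n_poor)) {
    rows[sprintf("poor%02d", i)] <- pad(mk_frag(sample(0:2, 1)))
  }
  for (i in seq_len(n_gappy)) {
    g <- strsplit(pad(mk_frag(5L)), "")[[1]]
    g[10] <- "."                      # gap inside the 34-column window
    rows[sprintf("gappy%02d", i)] <- paste(g, collapse = "")
  }
  rows
}

test_that("screen_family extracts the reference window and filters by count", {
  fam <- make_family_fixture()
  out <- screen_family(fam, "REF", rps20hhta_unit(), min_count = 3L)
  got <- sort(out$fragment_id)
  expect_identical(got, sort(c("REF", sprintf("rich%02d", 1:10))))
  expect_true(all(out$hydrophobic_count >= 3L))
  expect_identical(out$fragment[out$fragment_id == "REF"],
                   rps20hhta_unit())
  # gappy rows are discarded even with a perfect interface
  expect_false(any(grepl("gappy", out$fragment_id)))
  # ordering: counts descending, ties by id
  expect_true(all(diff(out$hydrophobic_count) <= 0))
})

test_that("screen output is invariant to row order and outside columns", {
  fam <- make_family_fixture()
  base <- screen_family(fam, "REF", rps20hhta_unit(), min_count = 3L)
  shuffled <- fam[sample(seq_along(fam))]
  expect_identical(
    screen_family(shuffled, "REF", rps20hhta_unit(), min_count = 3L), base)
  # scrambling the junk columns outside the window changes nothing
  scrambled <- vapply(fam, function(r) {
    paste0("ZZ", substr(r, 3, nchar(r) - 3), "QQQ")
  }, character(1))
  names(scrambled) <- names(fam)
  expect_identical(
    screen_family(scrambled, "REF", rps20hhta_unit(), min_count = 3L)[
      , c("fragment_id", "hydrophobic_count")],
    base[, c("fragment_id", "hydrophobic_count")])
})

test_that("min_count = 0 returns every indel-free row, matching a recount", {
  fam <- make_family_fixture()
  all_rows <- screen_family(fam, "REF", rps20hhta_unit(), min_count = 0L)
  expect_identical(nrow(all_rows), 1L + 10L + 15L)  # REF + rich + poor
  recount <- vapply(all_rows$fragment, function(f) {
    hydrophobic_interface_count(f)$hydrophobic_count
  }, integer(1))
  expect_identical(unname(recount), all_rows$hydrophobic_count)
})

test_that("screen_family validates the reference", {
  fam <- make_family_fixture()
  expect_error(screen_family(fam, "nope", rps20hhta_unit()),
               class = "tpr_reference_error")
  expect_error(screen_family(fam, "REF", strrep("W", 34)),
               class = "tpr_reference_error")
})

test_that("stockholm alignments are parsed like aligned FASTA", {
  fam <- make_family_fixture(n_rich = 2, n_poor = 2, n_gappy = 0)
  sto <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               "#=GF ID test",
               paste(names(fam), fam),
               "//"), sto)
  parsed <- read_alignment(sto)
  expect_identical(parsed, fam)
  out <- screen_family(parsed, "REF", rps20hhta_unit(), min_count = 0L)
  expect_identical(nrow(out), 5L)
})
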