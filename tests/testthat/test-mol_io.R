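# File-format readers and writers: PDB, OBJ, OpenDX, field-line JSON.

CA_LINE <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"

test_that("parse_pdb reads fixed-column atom records", {
  s <- parse_pdb(CA_LINE)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(unname(unlist(s$atoms[1, c("x", "y", "z")])), c(1, 2, 3))
  expect_equal(s$atoms$element, "C")
  expect_equal(s$atoms$name, "CA")
  expect_equal(s$atoms$res_name, "ALA")
  expect_equal(s$atoms$chain, "A")
  expect_false(s$atoms$is_hetero)
  expect_equal(nrow(s$bonds), 0L)
})

make_model_block <- function(model_no, n = 10) {
  recs <- sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                  seq_len(n), seq_len(n), seq_len(n) * 2, 0, model_no * 10)
  c(sprintf("MODEL     %4d", model_no), recs, "ENDMDL")
}

test_that("default policy keeps only the first MODEL", {
  txt <- paste(c(make_model_block(1), make_model_block(2)), collapse = "\n")
  s <- parse_pdb(txt)
  expect_equal(nrow(s$atoms), 10L)
  expect_true(all(s$atoms$z == 10))
  s_all <- parse_pdb(txt, pdb_policy(first_model_only = FALSE))
  expect_equal(nrow(s_all$atoms), 20L)
})

test_that("first alternate location per atom is kept", {
  txt <- paste(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CB  ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
    sep = "\n")
  s <- parse_pdb(txt)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$alt_loc[1], "A")
})

test_that("element falls back to the atom name when columns 77-78 are blank", {
  # hydrogen with a digit-bearing name, iron left-justified at column 13
  txt <- paste(
    "ATOM      1 1HB  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "HETATM    2 FE   HEM A   2       3.000   0.000   0.000  1.00  0.00",
    sep = "\n")
  s <- parse_pdb(txt)
  expect_equal(s$atoms$element, c("H", "FE"))
})

test_that("policy switches drop hetero, hydrogens and waters", {
  txt <- paste(
    CA_LINE,
    "ATOM      2  H   ALA A   1       1.500   2.000   3.000  1.00  0.00           H",
    "HETATM    3  O   HOH A 101       8.000   8.000   8.000  1.00  0.00           O",
    sep = "\n")
  expect_equal(nrow(parse_pdb(txt)$atoms), 3L)
  expect_equal(nrow(parse_pdb(txt, pdb_policy(keep_waters = FALSE))$atoms), 2L)
  expect_equal(nrow(parse_pdb(txt, pdb_policy(keep_hydrogens = FALSE))$atoms), 2L)
  expect_equal(nrow(parse_pdb(txt, pdb_policy(keep_hetero = FALSE))$atoms), 2L)
})

test_that("parse_pdb reports malformed and empty input", {
  bad <- "ATOM      1  CA  ALA A   1       1.0x0   2.000   3.000  1.00  0.00           C"
  expect_error(parse_pdb(bad), "line 1")
  expect_error(parse_pdb(""), "empty")
  expect_error(parse_pdb("REMARK nothing here"), "no ATOM")
})

test_that("parse_pdb preserves record order", {
  txt <- paste(sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f   0.000   0.000  1.00  0.00           C",
    c(5L, 2L, 9L), 1:3, c(1, 2, 3)), collapse = "\n")
  s <- parse_pdb(txt)
  expect_equal(s$atoms$serial, c(5L, 2L, 9L))
  expect_equal(s$atoms$x, c(1, 2, 3))
})

test_that("fetch_pdb validates its id and fails loudly", {
  expect_error(fetch_pdb("TOOLONG"), "4-character")
  expect_error(fetch_pdb(c("1ABC", "2DEF")), "4-character")
})

test_that("read_obj handles triangles, quads and negative indices", {
  m <- read_obj("v 0 0 0\nv 1 0 0\nv 0 1 0\nf 1 2 3")
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(m$faces, matrix(c(1L, 2L, 3L), 1))
  q <- read_obj("v 0 0 0\nv 1 0 0\nv 1 1 0\nv 0 1 0\nf 1 2 3 4")
  expect_equal(q$faces, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  neg <- read_obj("v 0 0 0\nv 1 0 0\nv 0 1 0\nf -3 -2 -1")
  expect_equal(neg$faces, matrix(c(1L, 2L, 3L), 1))
  expect_error(read_obj("v 0 0 0\nf 1 2 3"), "undefined vertex")
})

test_that("write_obj/read_obj round-trips vertices, faces and normals", {
  set.seed(42)
  v <- matrix(rnorm(30), ncol = 3)
  f <- rbind(c(1L, 2L, 3L), c(4L, 5L, 6L), c(7L, 8L, 9L))
  n <- matrix(rnorm(30), ncol = 3); n <- n / sqrt(rowSums(n^2))
  m <- triangle_mesh(v, f, n)
  m2 <- read_obj(write_obj(m))
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-8)
  expect_identical(m2$faces, m$faces)
  expect_equal(m2$normals, m$normals, tolerance = 1e-6)
  empty <- write_obj(triangle_mesh(matrix(numeric(0), ncol = 3),
                                   matrix(integer(0), ncol = 3)))
  expect_false(grepl("^v |\nf ", empty))
  one <- write_obj(triangle_mesh(diag(3), matrix(1:3, 1)))
  expect_equal(length(grep("^v ", strsplit(one, "\n")[[1]])), 3L)
  expect_equal(length(grep("^f ", strsplit(one, "\n")[[1]])), 1L)
})

opendx_2x2x2 <- paste(c(
  "object 1 class gridpositions counts 2 2 2", "origin 0 0 0",
  "delta 1 0 0", "delta 0 1 0", "delta 0 0 1",
  "object 2 class gridconnections counts 2 2 2",
  "object 3 class array type double rank 0 items 8 data follows",
  "0 1 2", "3 4 5", "6 7"), collapse = "\n")

test_that("read_opendx uses the z-fastest file layout", {
  g <- read_opendx(opendx_2x2x2)
  expect_equal(g$counts, c(2L, 2L, 2L))
  # value at 0-based index (1,0,0) is the fifth token (verified against an
  # independent OpenDX reader on the same text)
  expect_equal(g$values[2, 1, 1], 4)
  expect_equal(g$values[1, 1, 2], 1)
  expect_equal(g$values[1, 2, 1], 2)
})

test_that("read_opendx ignores comments and validates item counts", {
  with_comments <- paste0("# a comment\n# another\n", opendx_2x2x2)
  expect_equal(read_opendx(with_comments)$values, read_opendx(opendx_2x2x2)$values)
  short <- sub("6 7", "6", opendx_2x2x2)
  expect_error(read_opendx(short), "mismatch")
  skewed <- sub("delta 0 1 0", "delta 0.1 1 0", opendx_2x2x2)
  expect_error(read_opendx(skewed), "axis-aligned")
})

test_that("read_opendx preserves the total of the data section", {
  g <- make_point_charge_grid(q = 2, n = 12, extent = 10)
  txt <- write_opendx(g)
  g2 <- read_opendx(txt)
  data_lines <- strsplit(txt, "\n")[[1]]
  start <- grep("data follows", data_lines) + 1L
  end <- grep("attribute", data_lines) - 1L
  toks <- as.numeric(unlist(strsplit(trimws(data_lines[start:end]), "\\s+")))
  expect_equal(sum(g2$values), sum(toks), tolerance = 1e-9)
  expect_equal(g2$values, g$values, tolerance = 1e-8)
})

test_that("field-line JSON round-trips and validates", {
  one <- read_fieldlines_json('{"lines":[{"points":[[0,0,0],[1,0,0]]}]}')
  expect_length(one$lines, 1L)
  expect_equal(max(one$lines[[1]]$arclengths), 1.0)
  empty <- read_fieldlines_json('{"lines":[]}')
  expect_length(empty$lines, 0L)
  expect_error(read_fieldlines_json('{"lines":[{"points":[[0,0,0]]}]}'),
               "fewer than 2")
  expect_error(read_fieldlines_json('{"lines":[{"points":[[0,0,"a"],[1,0,0]]}]}'))
  set.seed(7)
  fl <- field_line(matrix(cumsum(runif(30)), ncol = 3))
  fls <- field_line_set(list(fl))
  back <- read_fieldlines_json(write_fieldlines_json(fls))
  expect_equal(back$lines[[1]]$points, fl$points, tolerance = 1e-9)
})
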