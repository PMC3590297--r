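# Headless rendering: chunking, ray-cast coverage, occlusion, cut
# planes, lit-sphere shading and PNG output.

test_that("chunk_particles yields balanced ranges below the limit", {
  ch <- chunk_particles(50000, 16000)
  expect_equal(nrow(ch), 4L)                       # ceiling(50000/16000)
  lens <- ch[, "end"] - ch[, "start"]
  expect_true(all(lens <= 16000))
  expect_lte(diff(range(lens)), 1)
  expect_equal(unname(ch[1, "start"]), 0L)
  expect_equal(unname(ch[nrow(ch), "end"]), 50000L)
  expect_true(all(ch[-1, "start"] == ch[-nrow(ch), "end"]))
  expect_equal(nrow(chunk_particles(16000, 16000)), 1L)
  expect_equal(nrow(chunk_particles(0, 16000)), 0L)
  expect_equal(nrow(chunk_particles(16001, 16000)), 2L)
})

unit_sphere_frames <- function(style = render_style(), cut = NULL,
                               width = 256, height = 256, hh = 2) {
  cam <- camera(eye = c(0, 0, 5), look_at = c(0, 0, 0),
                ortho_half_height = hh, width = width, height = height)
  render_scene(list(sphere_quadric(c(0, 0, 0), 1, c(1, 0, 0))),
               cam = cam, style = style, cut = cut)
}

test_that("orthographic sphere coverage matches the analytic disk area", {
  fr <- unit_sphere_frames()
  frac <- mean(fr$prim_id > 0)
  expect_lt(abs(frac - pi / 16) / (pi / 16), 0.01)  # pi r^2 / (4hh^2 aspect)
  # depth at the central pixel is eye-to-front-pole distance
  expect_equal(fr$depth[128, 128], 4, tolerance = 1e-3)
  # coverage consistency: covered <=> finite depth <=> unit normal
  cov <- fr$prim_id > 0
  expect_identical(cov, is.finite(fr$depth))
  nlen <- sqrt(fr$normal[, , 1]^2 + fr$normal[, , 2]^2 + fr$normal[, , 3]^2)
  expect_true(all(abs(nlen[cov] - 1) < 1e-9))
  expect_true(all(nlen[!cov] == 0))
})

test_that("an empty scene renders pure background", {
  st <- render_style(background = c(0.1, 0.2, 0.3))
  fr <- render_scene(list(), cam = camera(width = 32, height = 32), style = st)
  expect_true(all(fr$prim_id == 0L))
  expect_equal(fr$color[5, 5, ], c(0.1, 0.2, 0.3))
  expect_true(all(is.infinite(fr$depth)))
})

test_that("the depth buffer resolves occlusion", {
  cam <- camera(eye = c(0, 0, 10), ortho_half_height = 2, width = 64, height = 64)
  a <- sphere_quadric(c(0, 0, 2), 1, c(1, 0, 0))    # in front
  b <- sphere_quadric(c(0, 0, -2), 1.5, c(0, 1, 0)) # behind, larger
  fr <- render_scene(list(a, b), cam = cam, style = render_style())
  both <- fr$prim_id > 0
  # wherever the front sphere could cover (its disk), id must be 1
  sx <- ((col(fr$prim_id) - 0.5) / 64 - 0.5) * 4
  sy <- (0.5 - (row(fr$prim_id) - 0.5) / 64) * 4
  in_a <- sx^2 + sy^2 < 0.98^2
  expect_true(all(fr$prim_id[in_a] == 1L))
  expect_true(any(fr$prim_id == 2L))
})

test_that("chunked and unchunked particle renders are pixel-identical", {
  set.seed(17)
  prims <- lapply(1:40, function(i)
    sphere_quadric(c(runif(2, -1.5, 1.5), runif(1, -1, 1)), 0.25,
                   c(runif(3))))
  cam <- camera(eye = c(0, 0, 6), ortho_half_height = 2, width = 96, height = 96)
  st_all <- render_style(representation = "particle_spheres", chunk_limit = 1000)
  st_chunks <- render_style(representation = "particle_spheres", chunk_limit = 7)
  f1 <- render_scene(prims, cam = cam, style = st_all)
  f2 <- render_scene(prims, cam = cam, style = st_chunks)
  expect_identical(f1$color, f2$color)
  expect_identical(f1$depth, f2$depth)
  expect_identical(f1$prim_id, f2$prim_id)
})

test_that("rotating the camera 90 degrees rotates the id buffer 90 degrees", {
  prims <- list(sphere_quadric(c(1, 0.3, 0), 0.5, c(1, 0, 0)),
                sphere_quadric(c(-0.5, -1, 0.5), 0.7, c(0, 1, 0)))
  mk <- function(up) render_scene(prims,
    cam = camera(eye = c(0, 0, 6), up = up, ortho_half_height = 2,
                 width = 64, height = 64), style = render_style())
  f_up <- mk(c(0, 1, 0))
  f_rot <- mk(c(-1, 0, 0))   # screen rotated by 90 degrees
  # rotate the first id buffer by 90 degrees and compare
  rotated <- t(f_up$prim_id)[, rev(seq_len(64))]
  agree <- mean(rotated == f_rot$prim_id)
  expect_gt(agree, 0.995)    # boundary pixels may differ by quantization
})

test_that("a mid-sphere cut shows a cap disk of the analytic section area", {
  cut <- cut_plane(c(0, 0, 0), c(0, 0, 1), cap_color = c(0, 1, 0))
  fr <- unit_sphere_frames(cut = cut)
  px_area <- (4 / 256)^2
  want <- pi * 1^2 / px_area
  expect_lt(abs(sum(fr$cap) - want) / want, 0.02)
  # cap pixels are flat cap color
  capi <- which(fr$cap)
  HW <- 256 * 256
  expect_true(all(fr$color[capi] == 0))
  expect_true(all(fr$color[capi + HW] == 1))
  # an oblique cut leaves part of the surface shaded and part capped
  cut2 <- cut_plane(c(0, 0, 0), c(1, 0, 1) / sqrt(2), cap_color = c(0, 1, 0))
  fr2 <- unit_sphere_frames(cut = cut2)
  covered <- fr2$prim_id > 0
  expect_gt(sum(covered & !fr2$cap), 0)
  expect_gt(sum(fr2$cap), 0)
  # discarded side: fewer covered pixels than the uncut render
  expect_lt(sum(covered), sum(unit_sphere_frames()$prim_id > 0))
})

test_that("lit-sphere shading reproduces the texture on a full-frame sphere", {
  tex <- make_litsphere("hemilight", 256)
  st <- render_style(shading = "litsphere", litsphere_texture = tex,
                     litsphere_blend = 0)
  fr <- unit_sphere_frames(style = st, hh = 1)
  cov <- which(fr$prim_id > 0, arr.ind = TRUE)
  # oracle: bilinear resampling of the texture disk at pixel coordinates
  px <- (cov[, 2] - 0.5) / 256 * 2 - 1
  py <- 1 - (cov[, 1] - 0.5) / 256 * 2
  u <- (px + 1) / 2; v <- 1 - (py + 1) / 2
  want <- hyperview:::bilinear_texture(tex$pixels, u, v)
  got <- cbind(fr$color[cbind(cov, 1)], fr$color[cbind(cov, 2)],
               fr$color[cbind(cov, 3)])
  expect_lt(mean(abs(got - want)), 2 / 255)
})

test_that("a flat camera-facing mesh shades as the texture center; blend=1 is flat", {
  tex <- make_litsphere("checker", 64)
  quad <- triangle_mesh(rbind(c(-1, -1, 0), c(1, -1, 0), c(1, 1, 0), c(-1, 1, 0)),
                        rbind(c(1, 2, 3), c(1, 3, 4)),
                        normals = matrix(rep(c(0, 0, 1), 4), ncol = 3, byrow = TRUE))
  cam <- camera(eye = c(0, 0, 5), ortho_half_height = 0.9, width = 32, height = 32)
  st <- render_style(representation = "mesh", shading = "litsphere",
                     litsphere_texture = tex, litsphere_blend = 0)
  fr <- render_scene(meshes = list(list(mesh = quad, color = c(1, 0, 0))),
                     cam = cam, style = st)
  ctr_px <- tex$pixels[32, 32, ]   # normal (0,0,1) maps to the texture center
  expect_true(all(fr$prim_id > 0))
  for (ch in 1:3)
    expect_true(all(abs(fr$color[, , ch] - ctr_px[ch]) < 0.03))
  # blend = 1: flat base colors, texture ignored
  st1 <- render_style(representation = "mesh", shading = "litsphere",
                      litsphere_texture = tex, litsphere_blend = 1)
  fr1 <- render_scene(meshes = list(list(mesh = quad, color = c(1, 0, 0))),
                      cam = cam, style = st1)
  expect_true(all(fr1$color[, , 1] == 1))
  expect_true(all(fr1$color[, , 2] == 0))
})

test_that("mesh rasterization occludes against quadrics", {
  quad <- triangle_mesh(rbind(c(-2, -2, 2), c(2, -2, 2), c(2, 2, 2), c(-2, 2, 2)),
                        rbind(c(1, 2, 3), c(1, 3, 4)))
  cam <- camera(eye = c(0, 0, 6), ortho_half_height = 2, width = 48, height = 48)
  fr <- render_scene(list(sphere_quadric(c(0, 0, 0), 1, c(1, 0, 0))),
                     meshes = list(list(mesh = quad, color = c(0, 0, 1))),
                     cam = cam, style = render_style())
  # the plane at z=2 sits in front of the sphere everywhere
  expect_true(all(fr$prim_id == 2L))
})

test_that("write_png round-trips pixels and is deterministic", {
  set.seed(23)
  img <- array(runif(12 * 10 * 3), dim = c(12, 10, 3))
  img <- round(img * 255) / 255
  p1 <- tempfile(fileext = ".png"); p2 <- tempfile(fileext = ".png")
  write_png(img, p1); write_png(img, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_png(p1)
  expect_equal(back, img, tolerance = 1e-9)
  tiny <- tempfile(fileext = ".png")
  write_png(array(0.5, dim = c(1, 1, 3)), tiny)
  expect_equal(dim(read_png(tiny)), c(1, 1, 3))
  unlink(c(p1, p2, tiny))
})
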