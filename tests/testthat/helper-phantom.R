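# Shared phantom fixtures, built once per session.
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

test_atlas <- function() cached("atlas", generate_atlas(phantom_spec()))

test_atlas_surface <- function() cached("atlas_surface", {
  surface_from_volume(test_atlas()$volume, contour_params(threshold = 50))
})

# operator stand-in: nose-tip-centred face window on the projection plane
face_rect <- function(surf, view = "-y") {
  dm <- project_depth(surf, view, 1)
  ij <- which(dm$grid == min(dm$grid, na.rm = TRUE), arr.ind = TRUE)[1, ]
  u <- dm$u0 + (ij[1] - 1) * dm$cell_size
  v <- dm$v0 + (ij[2] - 1) * dm$cell_size
  c(u - 21, v - 10, u + 21, v + 20)
}

# operator stand-in: face band bracketing the eye-nose region
face_band <- function(surf) {
  nz <- surf[which.max(surf[, 2]), 3]
  band_spec(nz - 20, nz + 30)
}

full_band <- function(surf) band_spec(min(surf[, 3]), max(surf[, 3]))

# one full TSPR run against a derived subject; returns truth + fit errors
tspr_recovery <- function(scale, rotation, translation, defects = list(),
                          jitter = 0, seed = 1L, n_scale_steps = 3,
                          subject_view = "-y") {
  ph <- test_atlas()
  sa <- test_atlas_surface()
  sub <- derive_subject(ph$volume, ph$labels, scale = scale,
                        rotation = rotation, translation = translation,
                        defects = defects, seed = seed)
  ss <- surface_from_volume(sub$volume, contour_params(threshold = 50))
  if (jitter > 0) {
    set.seed(seed)
    sa <- sa + matrix(rnorm(length(sa), 0, jitter), nrow(sa))
    ss <- ss + matrix(rnorm(length(ss), 0, jitter), nrow(ss))
  }
  reg <- tspr_register(sa, ss,
                       feature_grid_spec(face_rect(sa)),
                       feature_grid_spec(face_rect(ss, subject_view)),
                       face_band(sa), full_band(ss),
                       n_scale_steps = n_scale_steps,
                       subject_view = subject_view)
  dec <- decompose_similarity(reg$final)
  tdec <- decompose_similarity(sub$truth$transform)
  list(reg = reg, subject = sub, atlas_surface = sa, subject_surface = ss,
       scale_error = abs(dec$scale - tdec$scale) / tdec$scale,
       rotation_error = rotation_angle(dec$rotation %*% t(tdec$rotation)),
       translation_error = sqrt(sum((dec$translation - tdec$translation)^2)))
}
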