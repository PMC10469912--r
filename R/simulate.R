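# Synthetic landmark-cohort generator: emulates the statistical structure the
# analysis assumes (group-specific mean-shape deformations, age/gender effects
# with per-individual random age slopes, directional + fluctuating asymmetry,
# per-group Marx-grade distributions, repeated photographs per patient).

sim_groups <- c("control", "MFDM", "NAFD", "TC", "CHARGE")

#' Stylized mean ear shape
#'
#' A hand-placed 41-point right-ear polyline in image-pixel coordinates
#' (x rightward, y downward, roughly a 200 x 300 px box), following the
#' template's seven curve segments. Only relative deformations of this base
#' shape matter downstream: all geometry is convention-free after Procrustes
#' superimposition.
#'
#' @param template an [default_template()] object.
#' @return 41 x 2 coordinate matrix.
#' @export
base_ear_shape <- function(template = default_template()) {
  arc <- function(cx, cy, rx, ry, from_deg, to_deg, n) {
    th <- seq(from_deg, to_deg, length.out = n) * pi / 180
    cbind(cx + rx * cos(th), cy + ry * sin(th))
  }
  pts <- rbind(
    arc(105, 150, 65, 115, 190, 420, 12),  # outer_helix: front, over top, down back
    arc(105, 148, 48, 92, 210, 400, 8),    # inner_helix
    arc(92, 262, 26, 26, 160, 20, 5),      # lobe
    arc(52, 165, 14, 14, 300, 420, 3),     # tragus
    arc(78, 222, 13, 13, 120, 220, 3),     # antitragus
    arc(75, 175, 35, 38, 250, 290, 3),     # crus_helicis
    arc(82, 172, 26, 36, 100, 340, 7)      # concha
  )
  dimnames(pts) <- list(template$point_names, c("x", "y"))
  pts
}

seg_idx <- function(template, name) template$segments[[name]]

rotate_about <- function(points, center, angle_deg) {
  th <- angle_deg * pi / 180
  r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(points, 2, center) %*% r, 2, center, `+`)
}

#' Group-specific mean-shape deformation field
#'
#' Fixed 41 x 2 displacement field added to the base shape for each diagnostic
#' group, scaled by the configuration's single `effect_scale` knob. The MFDM
#' field combines a clockwise concha rotation, a downward concha shift, lobe
#' enlargement and a slight helix thickening; the CHARGE field reshapes the
#' concha toward a triangle and shrinks the lobe with a thinner helix; the
#' NAFD and TC fields are attenuated MFDM-like fields with small distinct
#' components, so those groups overlap MFDM more than CHARGE does.
#'
#' @param group one of control, MFDM, NAFD, TC, CHARGE.
#' @param template an [default_template()] object.
#' @return 41 x 2 displacement matrix (zero for controls).
#' @export
group_deformation_field <- function(group, template = default_template()) {
  group <- match.arg(group, sim_groups)
  base <- base_ear_shape(template)
  field <- matrix(0, nrow(base), 2, dimnames = dimnames(base))
  if (group == "control") return(field)
  concha <- seg_idx(template, "concha")
  lobe <- seg_idx(template, "lobe")
  inner <- seg_idx(template, "inner_helix")
  ctr <- colMeans(base)

  mfdm_field <- function() {
    f <- matrix(0, nrow(base), 2)
    cc <- colMeans(base[concha, , drop = FALSE])
    f[concha, ] <- rotate_about(base[concha, , drop = FALSE], cc, 10) -
      base[concha, , drop = FALSE]
    f[concha, 2] <- f[concha, 2] + 8                       # vertical concha shift
    lc <- colMeans(base[lobe, , drop = FALSE])
    f[lobe, ] <- f[lobe, ] + 0.22 * sweep(base[lobe, , drop = FALSE], 2, lc)
    rad <- sweep(base[inner, , drop = FALSE], 2, ctr)
    rad <- rad / sqrt(rowSums(rad^2))
    f[inner, ] <- f[inner, ] + 2 * rad                     # thickened helix
    f
  }

  if (group == "MFDM") {
    field <- mfdm_field()
  } else if (group == "NAFD") {
    field <- 0.6 * mfdm_field()
    tragus <- seg_idx(template, "tragus")
    field[tragus, 2] <- field[tragus, 2] + 3
  } else if (group == "TC") {
    field <- 0.7 * mfdm_field()
    crus <- seg_idx(template, "crus_helicis")
    field[crus, 1] <- field[crus, 1] - 3
  } else if (group == "CHARGE") {
    cpts <- base[concha, , drop = FALSE]
    verts <- cpts[c(1, 4, 7), , drop = FALSE]              # triangular concha
    tri <- rbind(verts, verts[1, , drop = FALSE])
    target <- t(apply(cpts, 1, function(p) project_to_polyline(p, tri)))
    field[concha, ] <- target - cpts
    lc <- colMeans(base[lobe, , drop = FALSE])
    field[lobe, ] <- -0.25 * sweep(base[lobe, , drop = FALSE], 2, lc)
    rad <- sweep(base[inner, , drop = FALSE], 2, ctr)
    rad <- rad / sqrt(rowSums(rad^2))
    field[inner, ] <- field[inner, ] - 2 * rad             # thinner helix
  }
  field
}

project_to_polyline <- function(p, poly) {
  best <- NULL
  bestd <- Inf
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    q <- a + t * ab
    d <- sum((p - q)^2)
    if (d < bestd) { bestd <- d; best <- q }
  }
  best
}

unit_field <- function(f) f / sqrt(sum(f^2))

# covariate displacement fields, unit Frobenius norm so that configured
# slopes are exactly recoverable by projecting raw coordinates onto them
covariate_fields <- function(template = default_template()) {
  base <- base_ear_shape(template)
  lobe <- seg_idx(template, "lobe")
  outer <- seg_idx(template, "outer_helix")
  ctr <- colMeans(base)
  age <- matrix(0, nrow(base), 2)
  age[lobe, 2] <- 1                                        # lobe elongates with age
  age[outer, 2] <- 0.3 * sign(base[outer, 2] - ctr[2])
  gender <- matrix(0, nrow(base), 2)
  gender[outer, 1] <- sign(base[outer, 1] - ctr[1])        # males slightly wider
  da <- rotate_about(base, ctr, 2) - base                  # directional: small tilt
  list(age = unit_field(age), gender = unit_field(gender), da = unit_field(da))
}

#' Simulation configuration
#'
#' Validated parameter set for [simulate_cohort()]. Defaults reproduce the
#' study conditions of the training cohort: group sizes 471/31/9/15/24
#' (control/MFDM/NAFD/TC/CHARGE, scaled by `n_scale`), 1-5 photographs per
#' patient at increasing ages, a truncated log-normal age distribution matched
#' to mean 7.2 and SD 5.9 years (range 0-60.7), per-group proportions of
#' female patients 53/52/56/40/42 percent, and per-group Marx-grade
#' distributions whose pooled grade 0-I mass is 100/92/100/80/100 percent
#' (grade II 0/3/0/17/0, grade III 0/5/0/3/0, grade IV absent). MFDM genotype
#' classes follow the observed 11/9/7/4 split over splice, frameshift,
#' nonsense and deletion variants.
#'
#' @param group_sizes named integer vector of patients per group (any subset
#'   of control, MFDM, NAFD, TC, CHARGE).
#' @param n_scale multiplier applied to `group_sizes` (rounded, minimum 1 for
#'   nonzero groups).
#' @param photos_per_patient integer vector of admissible photo counts.
#' @param age_meanlog,age_sdlog,age_max log-normal age model (years).
#' @param p_female named per-group probability of a female patient.
#' @param grade_probabilities named list of per-group probabilities over Marx
#'   grades 0-4 (each summing to 1).
#' @param effect_scale multiplier on the group deformation fields (0 removes
#'   all group shape signal).
#' @param beta_age fixed age slope, px/year along the unit age field.
#' @param beta_gender male offset, px along the unit gender field.
#' @param sigma_slope SD of the per-individual random age slope (px/year).
#' @param da_offset directional-asymmetry offset applied to left ears, px.
#' @param fa_sd SD of the per-ear fluctuating-asymmetry displacement, px
#'   (drawn once per patient side, stable across photographs).
#' @param meas_sd per-photograph landmark measurement noise SD, px.
#' @param genotype_probs named probabilities over MFDM genotype classes.
#' @param role `"training"` (repeated photos, one random side each) or
#'   `"validation"` (exactly one photograph of each side per patient).
#' @param seed integer seed; the cohort is a pure function of the config.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(group_sizes = c(control = 471, MFDM = 31,
                                              NAFD = 9, TC = 15, CHARGE = 24),
                              n_scale = 1,
                              photos_per_patient = 1:5,
                              age_meanlog = 1.717, age_sdlog = 0.717,
                              age_max = 60.7,
                              p_female = c(control = 0.53, MFDM = 0.52,
                                           NAFD = 0.56, TC = 0.40, CHARGE = 0.42),
                              grade_probabilities = list(
                                control = c(0.95, 0.05, 0, 0, 0),
                                MFDM   = c(0.32, 0.60, 0.03, 0.05, 0),
                                NAFD   = c(0.40, 0.60, 0, 0, 0),
                                TC     = c(0.20, 0.60, 0.17, 0.03, 0),
                                CHARGE = c(0.40, 0.60, 0, 0, 0)),
                              effect_scale = 1,
                              beta_age = 0.6,
                              beta_gender = 3,
                              sigma_slope = 0.15,
                              da_offset = 1.5,
                              fa_sd = 1.2,
                              meas_sd = 1.0,
                              genotype_probs = c(splice = 11, frameshift = 9,
                                                 nonsense = 7, deletion = 4) / 31,
                              role = c("training", "validation"),
                              seed = 0L) {
  role <- match.arg(role)
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% sim_groups))
    stop("`group_sizes` must be named with groups among: ",
         paste(sim_groups, collapse = ", "), call. = FALSE)
  if (any(group_sizes < 0)) stop("group sizes must be >= 0.", call. = FALSE)
  group_sizes <- ifelse(group_sizes > 0, pmax(1L, round(group_sizes * n_scale)), 0L)
  for (g in names(group_sizes)) {
    pr <- grade_probabilities[[g]]
    if (is.null(pr) || length(pr) != 5L || any(pr < 0) || any(pr > 1) ||
        abs(sum(pr) - 1) > 1e-8)
      stop("grade probabilities for group '", g,
           "' must be 5 values in [0,1] summing to 1.", call. = FALSE)
    pf <- p_female[[g]]
    if (is.null(pf) || pf < 0 || pf > 1)
      stop("p_female for group '", g, "' must be in [0,1].", call. = FALSE)
  }
  if (any(c(sigma_slope, da_offset, fa_sd, meas_sd) < 0))
    stop("all noise SDs and offsets must be >= 0.", call. = FALSE)
  if (abs(sum(genotype_probs) - 1) > 1e-8 || any(genotype_probs < 0))
    stop("`genotype_probs` must be probabilities summing to 1.", call. = FALSE)
  structure(
    list(group_sizes = group_sizes, photos_per_patient = photos_per_patient,
         age_meanlog = age_meanlog, age_sdlog = age_sdlog, age_max = age_max,
         p_female = p_female, grade_probabilities = grade_probabilities,
         effect_scale = effect_scale, beta_age = beta_age,
         beta_gender = beta_gender, sigma_slope = sigma_slope,
         da_offset = da_offset, fa_sd = fa_sd, meas_sd = meas_sd,
         genotype_probs = genotype_probs, role = role, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$role, "cohort, seed", x$seed, "\n  patients:",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
            collapse = ", "),
      sprintf("\n  effect_scale=%.2f beta_age=%.2f beta_gender=%.2f sigma_slope=%.2f",
              x$effect_scale, x$beta_age, x$beta_gender, x$sigma_slope),
      sprintf("\n  da_offset=%.2f fa_sd=%.2f meas_sd=%.2f\n",
              x$da_offset, x$fa_sd, x$meas_sd))
  invisible(x)
}

truncated_lognormal <- function(n, meanlog, sdlog, upper) {
  out <- stats::rlnorm(n, meanlog, sdlog)
  bad <- out > upper
  while (any(bad)) {
    out[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
    bad <- out > upper
  }
  out
}

#' Simulate a landmark cohort
#'
#' Generates a cohort of ear photographs with the generative structure the
#' downstream analysis assumes. Per patient: gender, a baseline age, a
#' per-individual random age slope, per-side Marx grades and (for MFDM) a
#' genotype class are drawn. Per photograph: the age advances monotonically
#' and one ear is produced as
#' base shape + group deformation + (beta_age + individual slope) x age x age
#' field + gender offset + directional side offset + per-side fluctuating
#' displacement + measurement noise, generated in the right-ear frame and
#' mirrored for left ears. Ears of grade II or worse carry no landmarks.
#' The result is a pure function of the configuration (including its seed).
#'
#' @param config a [simulation_config()] object.
#' @return A tibble with one row per ear photograph: `patient_id`, `photo_id`,
#'   `side`, `age`, `gender`, `group`, `genotype_class`, `marx_grade` and a
#'   `landmarks` list-column of [ear_landmarks()] (or `NULL`). Attributes
#'   `role` and `config` carry the provenance.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  template <- default_template()
  base <- base_ear_shape(template)
  fields <- covariate_fields(template)
  withr::with_seed(config$seed, {
    rows <- list()
    for (g in names(config$group_sizes)) {
      ng <- config$group_sizes[[g]]
      if (ng == 0) next
      def <- config$effect_scale * group_deformation_field(g, template)
      for (i in seq_len(ng)) {
        pid <- sprintf("%s_%03d", g, i)
        gender <- if (stats::runif(1) < config$p_female[[g]]) "female" else "male"
        genotype <- if (g == "MFDM")
          sample(names(config$genotype_probs), 1, prob = config$genotype_probs)
        else "none"
        grades <- c(
          left = sample(0:4, 1, prob = config$grade_probabilities[[g]]),
          right = sample(0:4, 1, prob = config$grade_probabilities[[g]])
        )
        slope_i <- stats::rnorm(1, 0, config$sigma_slope)
        fa_disp <- list(
          left = matrix(stats::rnorm(82, 0, config$fa_sd), 41, 2),
          right = matrix(stats::rnorm(82, 0, config$fa_sd), 41, 2)
        )
        a0 <- truncated_lognormal(1, config$age_meanlog, config$age_sdlog,
                                  config$age_max)
        if (config$role == "validation") {
          occasions <- data.frame(age = rep(a0, 2), side = c("left", "right"))
        } else {
          np <- if (length(config$photos_per_patient) == 1L)
            config$photos_per_patient else sample(config$photos_per_patient, 1)
          ages <- pmin(a0 + c(0, cumsum(stats::rexp(np - 1, 1 / 1.5))),
                       config$age_max)
          occasions <- data.frame(age = ages,
                                  side = sample(c("left", "right"), np,
                                                replace = TRUE))
        }
        for (k in seq_len(nrow(occasions))) {
          side <- occasions$side[k]
          age <- occasions$age[k]
          grade <- grades[[side]]
          lm <- NULL
          if (grade <= 1L) {
            pts <- base + def +
              (config$beta_age + slope_i) * age * fields$age +
              (gender == "male") * config$beta_gender * fields$gender +
              (side == "left") * config$da_offset * fields$da +
              fa_disp[[side]] +
              matrix(stats::rnorm(82, 0, config$meas_sd), 41, 2)
            if (side == "left") pts[, 1] <- 210 - pts[, 1]
            lm <- ear_landmarks(pts, side = side, template = template)
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            patient_id = pid,
            photo_id = sprintf("%s_ph%02d_%s", pid, k, substr(side, 1, 1)),
            side = side, age = age, gender = gender, group = g,
            genotype_class = genotype, marx_grade = as.integer(grade),
            landmarks = list(lm)
          )
        }
      }
    }
    cohort <- dplyr::bind_rows(rows)
  })
  attr(cohort, "role") <- config$role
  attr(cohort, "config") <- config
  cohort
}

#' Published validation-set confusion matrices
#'
#' The three confusion matrices reported for the validation set (prediction
#' rows by reference columns, label order as printed): the binary
#' MFDM-vs-control design, the four-class design with controls, and the
#' three-class differential-diagnosis design. These serve as fixtures for the
#' evaluation engine: every derivable published metric (accuracy and its
#' exact interval, sensitivity, specificity, balanced accuracy, the
#' no-information-rate test) is recomputed from them.
#'
#' @return Named list of integer matrices `design1`, `design2.1`, `design2.2`.
#' @export
paper_confusion_fixtures <- function() {
  d1 <- matrix(c(10, 0,
                 1, 21), 2, 2, byrow = TRUE,
               dimnames = list(prediction = c("MFDM", "Control"),
                               reference = c("MFDM", "Control")))
  d21 <- matrix(c(4, 0, 1, 0,
                  0, 21, 2, 0,
                  1, 0, 4, 1,
                  2, 0, 0, 1), 4, 4, byrow = TRUE,
                dimnames = list(prediction = c("MFDM", "Control", "CHARGE", "TC"),
                                reference = c("MFDM", "Control", "CHARGE", "TC")))
  d22 <- matrix(c(7, 0, 1,
                  0, 6, 1,
                  0, 1, 0), 3, 3, byrow = TRUE,
                dimnames = list(prediction = c("MFDM", "CHARGE", "TC"),
                                reference = c("MFDM", "CHARGE", "TC")))
  list(design1 = d1, design2.1 = d21, design2.2 = d22)
}
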