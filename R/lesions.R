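# ---------------------------------------------------------------------------
# Ablation lesion sets: PVI, MIL, AL, RL, BL realized as transmural element
# masks on the idealized shell.  Lesion paths are geodesics between anatomical
# landmarks on the shell midsurface, dilated to the requested width; masks are
# defined on midsurface footprints, so transmurality holds by construction.
# ---------------------------------------------------------------------------

#' Names of the ten studied ablation cases
#'
#' @return character vector: Control plus the nine lesion combinations
#' @export
lesion_case_names <- function() {
  c("Control", "PVI", "PVI+BL", "PVI+AL", "PVI+AL+BL", "PVI+AL+RL",
    "PVI+MIL", "PVI+MIL+BL", "PVI+MIL+RL", "PVI+RL")
}

normalize_case_name <- function(case_name) {
  nm <- gsub("\\s+", "", case_name)
  known <- lesion_case_names()
  hit <- match(tolower(nm), tolower(gsub("\\s+", "", known)))
  if (is.na(hit)) stop("unknown lesion case: ", case_name,
                       " (known: ", paste(known, collapse = ", "), ")")
  known[hit]
}

geodesic_band <- function(dirs, u, v, halfwidth_ang) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  nrm <- crossprod_3(u, v)
  sinuv <- sqrt(sum(nrm^2))
  Delta <- atan2(sinuv, sum(u * v))
  nrm <- nrm / sinuv
  w <- crossprod_3(nrm, u)                      # in-plane, perpendicular to u
  xt <- asin(pmin(1, pmax(-1, dirs %*% nrm)))   # cross-track angle
  at <- atan2(dirs %*% w, dirs %*% u)           # along-track angle
  seg <- abs(xt) <= halfwidth_ang & at >= 0 & at <= Delta
  cap <- angdist(dirs, u) <= halfwidth_ang | angdist(dirs, v) <= halfwidth_ang
  as.logical(seg | cap)
}

#' Build a single ablation lesion mask
#'
#' Realizes one of the five standard left-atrial lesions as a transmural
#' element mask: pulmonary vein isolation (PVI, a closed band encircling each
#' ostium), mitral isthmus line (MIL, annulus to left inferior vein), anterior
#' line (AL, annulus to left superior vein across the anterior wall), roof
#' line (RL, joining the two superior veins over the roof), and posterior box
#' lesion (BL, the RL plus an inferior line joining the inferior veins; with
#' PVI these close the posterior box).  BL therefore contains RL element-wise.
#'
#' @param mesh LA shell `labeled_mesh` (mechanics or nested EP mesh)
#' @param lesion one of "PVI", "MIL", "AL", "RL", "BL"
#' @param width average lesion width (mm), default 5; applied transmurally
#' @return logical element mask
#' @export
build_lesion <- function(mesh, lesion = c("PVI", "MIL", "AL", "RL", "BL"),
                         width = 5) {
  lesion <- match.arg(lesion)
  meta <- mesh$meta
  if (is.null(meta) || !identical(meta$kind, "la_shell"))
    stop("lesions require the idealized LA shell (missing landmarks)")
  if (width <= 0) stop("lesion width must be positive (empty mask rejected)")
  if (width < 0.8 * meta$resolution)
    stop("lesion width ", width, " mm is below the mesh resolution ",
         meta$resolution, " mm and cannot be resolved")
  anat <- meta$anatomy
  dirs <- cbind(mesh$aux$dx, mesh$aux$dy, mesh$aux$dz)
  hw <- (width / 2) / meta$radius
  hole <- meta$hole_ang
  mask <- switch(lesion,
    PVI = {
      m <- rep(FALSE, nrow(dirs))
      for (nm in names(anat$pv)) {
        a <- angdist(dirs, anat$pv[[nm]])
        m <- m | (a < hole + 2 * hw)   # band hugging the ostium rim
      }
      m
    },
    RL = geodesic_band(dirs, anat$pv$rspv, anat$pv$lspv, hw),
    BL = geodesic_band(dirs, anat$pv$rspv, anat$pv$lspv, hw) |
         geodesic_band(dirs, anat$pv$ripv, anat$pv$lipv, hw),
    AL = {
      # anterior line climbs the anterior meridian from the annulus to the
      # roof, then joins the left superior vein; a single great circle
      # between the anchors would cut the lateral wall instead
      waypoint <- c(sin(8 * pi / 180) * cos(270 * pi / 180),
                    sin(8 * pi / 180) * sin(270 * pi / 180),
                    cos(8 * pi / 180))
      geodesic_band(dirs, anat$al_annulus, waypoint, hw) |
        geodesic_band(dirs, waypoint, anat$pv$lspv, hw)
    },
    MIL = geodesic_band(dirs, anat$mil_annulus, anat$pv$lipv, hw))
  mask & mesh$region == "LA"
}

#' Combine component lesions into a named ablation case
#'
#' The ten studied cases are Control plus nine combinations of the five
#' component lesions; a case mask is the union of its component masks.  When
#' given the nested EP mesh, the mechanics mask is obtained by volume-majority
#' vote over each mechanics element's EP children (near-exact for nested
#' meshes).
#'
#' @param mesh LA shell mesh; if it carries `ep_to_mech_map`, both the EP and
#'   mechanics masks are produced
#' @param case_name one of the ten case names, e.g. "PVI+AL+BL" (spaces
#'   around "+" are accepted)
#' @param width average lesion width (mm)
#' @param width_scale named per-lesion width multipliers (calibration knob)
#' @return a `lesion_set`
#' @export
combine_lesions <- function(mesh, case_name, width = 5, width_scale = NULL) {
  case_name <- normalize_case_name(case_name)
  comps <- if (case_name == "Control") character(0) else
    strsplit(case_name, "+", fixed = TRUE)[[1]]
  ne <- n_elements(mesh)
  ep_mask <- rep(FALSE, ne)
  for (cmp in comps) {
    w <- width * if (!is.null(width_scale) && cmp %in% names(width_scale))
      width_scale[[cmp]] else 1
    ep_mask <- ep_mask | build_lesion(mesh, cmp, width = w)
  }
  if (!is.null(mesh$ep_to_mech_map)) {
    vol <- abs(tet_volumes(mesh))
    tot <- tapply(vol, mesh$ep_to_mech_map, sum)
    les <- tapply(vol * ep_mask, mesh$ep_to_mech_map, sum)
    mech_mask <- as.numeric(les / tot) > 0.5
  } else mech_mask <- ep_mask
  structure(list(name = case_name, component_lesions = comps,
                 ep_mask = ep_mask, mech_mask = mech_mask, width = width),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cat("lesion_set:", x$name, "\n")
  cat("  components:", if (length(x$component_lesions))
    paste(x$component_lesions, collapse = " + ") else "(none)", "\n")
  cat("  EP mask:", sum(x$ep_mask), "of", length(x$ep_mask), "elements\n")
  cat("  mechanics mask:", sum(x$mech_mask), "of", length(x$mech_mask),
      "elements\n")
  invisible(x)
}

#' Ablated-tissue fraction
#'
#' Percentage of left-atrial myocardial volume covered by the lesion set.
#'
#' @param mesh the mesh the lesion's EP mask refers to
#' @param lesions a `lesion_set` (or a logical element mask)
#' @return percentage in [0, 100]
#' @export
ablated_fraction <- function(mesh, lesions) {
  mask <- if (inherits(lesions, "lesion_set")) lesions$ep_mask else lesions
  vol <- abs(tet_volumes(mesh))
  myo <- mesh$region == "LA"
  tot <- sum(vol[myo])
  if (tot <= 0) stop("zero myocardial volume")
  100 * sum(vol[mask & myo]) / tot
}

# Element adjacency graph restricted to non-masked elements; used to verify
# that lesion bands electrically separate regions (e.g. PVI loop closure).
element_adjacency <- function(mesh) {
  f <- tet_faces(mesh$tets)
  k <- face_key(f)
  owner <- rep(seq_len(n_elements(mesh)), 4L)
  o <- order(k)
  k <- k[o]; owner <- owner[o]
  same <- k[-1] == k[-length(k)]
  cbind(owner[c(same, FALSE)], owner[c(FALSE, same)])
}

# TRUE if some element of set `from` reaches some element of `to` through
# face-adjacent elements not in `blocked`.
elements_connected <- function(mesh, from, to, blocked) {
  adj <- element_adjacency(mesh)
  keep <- !(blocked[adj[, 1]] | blocked[adj[, 2]])
  adj <- adj[keep, , drop = FALSE]
  ne <- n_elements(mesh)
  nbr <- split(c(adj[, 2], adj[, 1]), c(adj[, 1], adj[, 2]))
  visited <- rep(FALSE, ne)
  queue <- setdiff(from, which(blocked))
  visited[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (cur %in% to) return(TRUE)
    nb <- nbr[[as.character(cur)]]
    nb <- nb[!visited[nb]]
    visited[nb] <- TRUE
    queue <- c(queue, nb)
  }
  any(visited[to])
}
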