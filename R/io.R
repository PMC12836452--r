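# Text-format writers/readers for meshes, panels and scenarios: VTU (ascii
# XML) and Gmsh MSH 2.2 for volumetric meshes with region labels, SVG for
# 2-D panel previews, YAML for scenario files.

#' Write a mesh (optionally deformed) as ascii VTU
#'
#' Quadratic tetrahedra (VTK cell type 24) with the region label and any
#' per-element fields as cell data.
#'
#' @param mesh \code{\link{lv_mesh}}
#' @param file output path
#' @param u optional displacement vector; written as point data and added
#'   to the coordinates when \code{deformed = TRUE}
#' @param cell_data named list of per-element numeric vectors
#' @param deformed write deformed coordinates
#' @export
write_vtu <- function(mesh, file, u = NULL, cell_data = list(),
                      deformed = FALSE) {
  nodes <- mesh$nodes
  if (!is.null(u) && deformed) nodes <- nodes + matrix(u, ncol = 3, byrow = TRUE)
  ne <- nrow(mesh$elems); nn <- nrow(nodes)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="', nn, '" NumberOfCells="', ne, '">')
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(nodes, 1, paste, collapse = " "), con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$elems - 1L, 1, paste, collapse = " "), con)
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(ne) * 10L), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(24L, ne)), con)
  w('</DataArray></Cells>')
  if (!is.null(u)) {
    w('<PointData><DataArray type="Float64" Name="displacement" NumberOfComponents="3" format="ascii">')
    writeLines(apply(matrix(u, ncol = 3, byrow = TRUE), 1,
                     paste, collapse = " "), con)
    w('</DataArray></PointData>')
  }
  w('<CellData>')
  w('<DataArray type="Int32" Name="region" format="ascii">')
  writeLines(paste(as.integer(factor(mesh$region,
                                     levels = c("remote", "infarct", "sleeve")))),
             con)
  w('</DataArray>')
  for (nm in names(cell_data)) {
    w('<DataArray type="Float64" Name="', nm, '" format="ascii">')
    writeLines(paste(cell_data[[nm]]), con)
    w('</DataArray>')
  }
  w('</CellData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(file)
}

# Gmsh tet10 ordering swaps the last two midside nodes relative to VTK
GMSH_TET10_PERM <- c(1:8, 10, 9)

#' Write a mesh as Gmsh MSH 2.2 (ascii)
#'
#' Region labels become physical tags (remote 1, infarct 2, sleeve 3).
#'
#' @param mesh \code{\link{lv_mesh}}
#' @param file output path
#' @export
write_msh <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("$MeshFormat"); w("2.2 0 8"); w("$EndMeshFormat")
  w("$Nodes"); w(nrow(mesh$nodes))
  writeLines(paste(seq_len(nrow(mesh$nodes)),
                   mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  w("$EndNodes")
  w("$Elements"); w(nrow(mesh$elems))
  tag <- as.integer(factor(mesh$region,
                           levels = c("remote", "infarct", "sleeve")))
  conn <- mesh$elems[, GMSH_TET10_PERM, drop = FALSE]
  writeLines(paste(seq_len(nrow(conn)), 11, 2, tag, tag,
                   apply(conn, 1, paste, collapse = " ")), con)
  w("$EndElements")
  invisible(file)
}

#' Read a Gmsh MSH 2.2 mesh written by \code{\link{write_msh}}
#'
#' @param file path
#' @return list with \code{nodes}, tet10 \code{elems} (VTK ordering) and
#'   \code{region}
#' @export
read_msh <- function(file) {
  ln <- readLines(file)
  i_n <- which(ln == "$Nodes"); i_en <- which(ln == "$EndNodes")
  nn <- as.integer(ln[i_n + 1])
  nd <- utils::read.table(text = ln[(i_n + 2):(i_en - 1)])
  nodes <- as.matrix(nd[order(nd[[1]]), 2:4])
  dimnames(nodes) <- NULL
  i_e <- which(ln == "$Elements"); i_ee <- which(ln == "$EndElements")
  el <- utils::read.table(text = ln[(i_e + 2):(i_ee - 1)])
  if (any(el[[2]] != 11)) stop("only 10-node tetrahedra are supported")
  ntags <- el[[3]]
  stopifnot(all(ntags == ntags[1]))
  off <- 3 + ntags[1]
  conn <- as.matrix(el[, (off + 1):(off + 10)])
  conn <- conn[, order(GMSH_TET10_PERM), drop = FALSE]
  dimnames(conn) <- NULL
  region <- c("remote", "infarct", "sleeve")[el[[4]]]
  list(nodes = nodes, elems = conn, region = region)
}

#' Write a 2-D panel as SVG (fabrication preview)
#'
#' @param panel \code{\link{tile_panel}} result
#' @param file output path
#' @param stroke outline colour
#' @export
write_panel_svg <- function(panel, file, stroke = "black") {
  polys <- panel$polygons
  allp <- do.call(rbind, polys)
  mn <- apply(allp, 2, min); mx <- apply(allp, 2, max)
  pad <- 0.05 * max(mx - mn)
  con <- file(file, "w")
  on.exit(close(con))
  cat(sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="%f %f %f %f">\n',
              mn[1] - pad, mn[2] - pad,
              (mx[1] - mn[1]) + 2 * pad, (mx[2] - mn[2]) + 2 * pad),
      file = con)
  for (p in polys) {
    pts <- paste(apply(p, 1, function(r) sprintf("%.6f,%.6f", r[1], r[2])),
                 collapse = " ")
    cat(sprintf('<polygon points="%s" fill="lightgray" stroke="%s" stroke-width="0.02"/>\n',
                pts, stroke), file = con)
  }
  cat("</svg>\n", file = con)
  invisible(file)
}

#' Write a scenario to YAML
#'
#' @param sc \code{\link{make_scenario}} result
#' @param file output path
#' @export
write_scenario_yaml <- function(sc, file) {
  stopifnot(inherits(sc, "scenario"))
  x <- list(
    name = sc$name,
    geometry = unclass(sc$geometry),
    infarct = unclass(sc$infarct),
    sleeve = if (!is.null(sc$sleeve)) {
      s <- unclass(sc$sleeve); s$cell <- unclass(s$cell); s
    },
    helix = as.list(sc$helix),
    materials = sc$materials,
    active = sc$active,
    pressure = sc$pressure,
    mesh = sc$mesh,
    n_steps = sc$n_steps,
    seed = sc$seed)
  yaml::write_yaml(x, file)
  invisible(file)
}

#' Read a scenario from YAML
#'
#' @param file path written by \code{\link{write_scenario_yaml}}
#' @return \code{scenario} object
#' @export
read_scenario_yaml <- function(file) {
  x <- yaml::read_yaml(file)
  sc <- make_scenario(
    name = x$name,
    zeta = if (!is.null(x$sleeve)) x$sleeve$zeta else 5,
    theta_sleeve_deg = if (!is.null(x$sleeve)) x$sleeve$angle_deg else 0,
    n_steps = x$n_steps,
    n_theta = x$mesh$n_theta, n_phi = x$mesh$n_phi,
    n_layers = x$mesh$n_layers,
    scale = x$geometry$scale,
    T_Ca_peak = x$active$T_Ca_peak,
    EDP = x$pressure$EDP, P_sys = x$pressure$P_sys,
    ref_stretch = if (is.null(x$active$ref_stretch)) NA
      else x$active$ref_stretch,
    sub = if (!is.null(x$sleeve)) x$sleeve$sub else 0,
    seed = x$seed)
  sc$geometry <- do.call(lv_geometry_spec,
                         x$geometry[c("R_epi", "H_epi", "T_base", "T_apex",
                                      "theta_max", "scale")])
  sc$infarct <- do.call(infarct_spec, x$infarct)
  sc
}

#' Write cycle metrics of a run bundle as CSV files
#'
#' @param bundle \code{\link{run_scenario}} result
#' @param dir output directory (created if needed)
#' @export
write_bundle_csv <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cyc <- bundle$cycle
  utils::write.csv(data.frame(time = cyc$time, V_mm3 = cyc$V,
                              P_kPa = cyc$P, T_Ca = cyc$T_Ca),
                   file.path(dir, "pv_trace.csv"), row.names = FALSE)
  utils::write.csv(bundle$regional_es,
                   file.path(dir, "regional_eff_es.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$torsion),
                   file.path(dir, "torsion.csv"), row.names = FALSE)
  pv <- bundle$pv
  utils::write.csv(data.frame(EDV_mL = pv$EDV, ESV_mL = pv$ESV,
                              SV_mL = pv$SV, EF_pct = pv$EF),
                   file.path(dir, "pv_metrics.csv"), row.names = FALSE)
  invisible(dir)
}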