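# ---------------------------------------------------------------------------
# Mesh writers/readers: VTK XML unstructured grid (.vtu, ascii) and Gmsh MSH
# v4.1.  Cell-data arrays "region", "fiber", "sheet", "normal" (and "scar"
# masks) are written alongside the connectivity.  Indices follow each
# format's convention (VTU 0-based, MSH 1-based).
# ---------------------------------------------------------------------------

#' Write a mesh as VTK XML unstructured grid (ascii .vtu)
#'
#' @param mesh a `labeled_mesh`
#' @param path output file
#' @param cell_data named list of extra per-element arrays (numeric vectors
#'   or n x 3 matrices), e.g. `list(scar = mask)`
#' @param point_data named list of per-vertex arrays (e.g. activation times)
#' @export
write_vtu <- function(mesh, path, cell_data = list(), point_data = list()) {
  nv <- n_vertices(mesh); ne <- n_elements(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  num <- function(x) paste(format(x, digits = 10, trim = TRUE,
                                  scientific = FALSE), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nv, ne))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w("          ", num(t(mesh$vertices)))
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  w("          ", paste(t(mesh$tets) - 1L, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  w("          ", paste(seq_len(ne) * 4L, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  w("          ", paste(rep(10L, ne), collapse = " "))  # VTK_TETRA
  w('        </DataArray>')
  w('      </Cells>')
  cd <- cell_data
  cd$region <- as.integer(factor(mesh$region))
  if (!is.null(mesh$frame)) {
    cd$fiber <- mesh$frame$f0
    cd$sheet <- mesh$frame$s0
    cd$normal <- mesh$frame$n0
  }
  w('      <CellData>')
  for (nm in names(cd)) {
    x <- cd[[nm]]
    ncomp <- if (is.null(dim(x))) 1L else ncol(x)
    w(sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
              nm, ncomp))
    w("          ", num(if (ncomp > 1) t(x) else as.numeric(x)))
    w('        </DataArray>')
  }
  w('      </CellData>')
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      x <- point_data[[nm]]
      ncomp <- if (is.null(dim(x))) 1L else ncol(x)
      w(sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
                nm, ncomp))
      w("          ", num(if (ncomp > 1) t(x) else as.numeric(x)))
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Read a VTK XML unstructured tetrahedral mesh (ascii .vtu)
#'
#' @param path file written by [write_vtu()] (or any ascii tetrahedral .vtu)
#' @return a `labeled_mesh` (region/frames restored when present)
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  getarr <- function(xpath) {
    nd <- xml2::xml_find_first(piece, xpath)
    if (is.na(nd)) return(NULL)
    scan(text = xml2::xml_text(nd), quiet = TRUE)
  }
  pts <- matrix(getarr(".//Points/DataArray"), ncol = 3, byrow = TRUE)
  conn <- getarr(".//Cells/DataArray[@Name='connectivity']")
  tets <- matrix(as.integer(conn) + 1L, ncol = 4, byrow = TRUE)
  mesh <- new_labeled_mesh(pts, tets, region = rep("LA", nrow(tets)))
  reg <- getarr(".//CellData/DataArray[@Name='region']")
  if (!is.null(reg)) mesh$region <- as.character(reg)
  f0 <- getarr(".//CellData/DataArray[@Name='fiber']")
  s0 <- getarr(".//CellData/DataArray[@Name='sheet']")
  if (!is.null(f0) && !is.null(s0))
    mesh$frame <- orthonormalize_frame(matrix(f0, ncol = 3, byrow = TRUE),
                                       matrix(s0, ncol = 3, byrow = TRUE))
  mesh
}

#' Write a mesh in Gmsh MSH 4.1 ascii format
#'
#' Single entity block of tetrahedra (element type 4), 1-based node tags.
#'
#' @param mesh a `labeled_mesh`
#' @param path output file
#' @export
write_msh <- function(mesh, path) {
  nv <- n_vertices(mesh); ne <- n_elements(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
  w("$Nodes")
  w(sprintf("1 %d 1 %d", nv, nv))       # 1 entity block
  w(sprintf("3 1 0 %d", nv))            # dim=3, tag=1, no parametric
  writeLines(as.character(seq_len(nv)), con)
  writeLines(apply(format(mesh$vertices, digits = 10, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  w("$EndNodes")
  w("$Elements")
  w(sprintf("1 %d 1 %d", ne, ne))
  w(sprintf("3 1 4 %d", ne))            # dim=3, tag=1, type 4 = tetra
  writeLines(paste(seq_len(ne), mesh$tets[, 1], mesh$tets[, 2],
                   mesh$tets[, 3], mesh$tets[, 4]), con)
  w("$EndElements")
  invisible(path)
}

#' Read a Gmsh MSH 4.1 ascii tetrahedral mesh
#'
#' @param path file written by [write_msh()] (single-block tetrahedral mesh)
#' @return a `labeled_mesh`
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  ni <- which(lines == "$Nodes"); ei <- which(lines == "$Elements")
  hdr <- scan(text = lines[ni + 1], quiet = TRUE)
  nv <- hdr[2]
  blk <- scan(text = lines[ni + 2], quiet = TRUE)
  nblk <- blk[4]
  coords <- lines[(ni + 3 + nblk):(ni + 2 + 2 * nblk)]
  pts <- matrix(scan(text = paste(coords, collapse = " "), quiet = TRUE),
                ncol = 3, byrow = TRUE)
  ehdr <- scan(text = lines[ei + 2], quiet = TRUE)
  nel <- ehdr[4]
  el <- matrix(scan(text = paste(lines[(ei + 3):(ei + 2 + nel)],
                                 collapse = " "), quiet = TRUE),
               ncol = 5, byrow = TRUE)
  new_labeled_mesh(pts, el[, 2:5, drop = FALSE],
                   region = rep("LA", nrow(el)))
}
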