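# Monosaccharide vocabulary shared by structures, generators and the
# activity registry. Ring size follows the drawing convention that the
# polygon has as many sides as the sugar has carbons; ketoses (Fru) carry
# their anomeric centre at C2.

.SUGARS <- data.frame(
  sugar           = c("Glc", "Gal", "Man", "Xyl", "Ara", "Fru",
                      "Rha", "Fuc", "GalA", "GlcA", "MeGlcA"),
  ring_carbons    = c(6L, 6L, 6L, 5L, 5L, 6L, 6L, 6L, 6L, 6L, 6L),
  anomeric_carbon = c(1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L),
  stringsAsFactors = FALSE
)

.MODIFICATIONS <- c("acetyl", "methyl", "feruloyl")
.CONFIGS <- c("alpha", "beta")
.ALPHA <- "α"
.BETA  <- "β"

.sugarInfo <- function(sugar) {
  i <- match(sugar, .SUGARS$sugar)
  if (anyNA(i)) {
    stop("unknown sugar code(s): ",
         paste(unique(sugar[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  .SUGARS[i, , drop = FALSE]
}

.configSymbol <- function(config) {
  ifelse(config == "alpha", .ALPHA, .BETA)
}

#' Compose the display label of a glycosidic bond
#'
#' Bond labels read child-first: `"Gal-α-1,6-Man"` is a galactose
#' attached through its anomeric carbon 1 in alpha configuration to carbon 6
#' of a mannose. Fructans yield labels such as `"Fru-β-2,1-Glc"` because
#' the ketose anomeric carbon is C2.
#'
#' @param child_sugar,parent_sugar monosaccharide codes.
#' @param config `"alpha"` or `"beta"`.
#' @param child_carbon anomeric carbon of the child residue.
#' @param parent_carbon carbon of the parent residue carrying the bond.
#' @return character vector of bond labels.
#' @export
bondLabel <- function(child_sugar, config, child_carbon, parent_carbon,
                      parent_sugar) {
  paste0(child_sugar, "-", .configSymbol(config), "-",
         child_carbon, ",", parent_carbon, "-", parent_sugar)
}

.modClassLabel <- function(kind, sugar) paste0(kind, "@", sugar)
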