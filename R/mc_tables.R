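# Marching-cubes connectivity for the 256 corner configurations of a 2x2x2
# voxel cell. Corner bit b = dx + 2*dy + 4*dz; edge ids 0..11 (see .mc_edge_*).
# Triangles are flat integer vectors of edge ids, 3 per triangle,
# oriented so outward normals give positive enclosed volume.
.mc_tri_edges <- list(
  integer(0),
  c(4,8,0L),
  c(0,9,5L),
  c(8,9,4,9,5,4L),
  c(10,4,1L),
  c(10,8,1,8,0,1L),
  c(5,0,9,10,4,1L),
  c(5,1,9,9,1,10,9,10,8L),
  c(1,5,11L),
  c(0,4,8,11,1,5L),
  c(9,11,0,11,1,0L),
  c(1,4,11,11,4,8,11,8,9L),
  c(4,5,10,5,11,10L),
  c(0,5,8,8,5,11,8,11,10L),
  c(4,0,10,10,0,9,10,9,11L),
  c(10,8,9,10,9,11L),
  c(2,8,6L),
  c(4,6,0,6,2,0L),
  c(2,8,6,5,0,9L),
  c(2,9,6,6,9,5,6,5,4L),
  c(8,6,2,1,10,4L),
  c(10,6,1,1,6,2,1,2,0L),
  c(6,2,8,5,0,9,1,10,4L),
  c(1,9,5,1,2,9,10,2,1,6,2,10L),
  c(2,8,6,11,1,5L),
  c(2,0,6,6,0,4,11,1,5L),
  c(1,0,11,11,0,9,6,2,8L),
  c(11,2,9,4,2,11,6,2,4,11,1,4L),
  c(11,10,5,5,10,4,2,8,6L),
  c(10,6,11,11,6,0,0,6,2,11,0,5L),
  c(8,6,2,9,10,4,11,10,9,0,9,4L),
  c(9,6,2,10,6,9,11,10,9L),
  c(9,2,7L),
  c(9,2,7,4,8,0L),
  c(0,2,5,2,7,5L),
  c(8,2,4,4,2,7,4,7,5L),
  c(9,2,7,1,10,4L),
  c(10,8,1,1,8,0,7,9,2L),
  c(7,5,2,2,5,0,10,4,1L),
  c(5,2,7,10,2,5,8,2,10,1,10,5L),
  c(7,9,2,1,5,11L),
  c(4,8,0,7,9,2,11,1,5L),
  c(7,11,2,2,11,1,2,1,0L),
  c(1,4,11,4,8,11,11,8,7,7,8,2L),
  c(4,5,10,10,5,11,2,7,9L),
  c(9,2,7,11,8,0,10,8,11,5,11,0L),
  c(2,7,0,0,7,10,10,7,11,10,4,0L),
  c(11,2,7,8,2,11,10,8,11L),
  c(9,8,7,8,6,7L),
  c(9,0,7,7,0,4,7,4,6L),
  c(0,8,5,5,8,6,5,6,7L),
  c(4,6,7,5,4,7L),
  c(9,8,7,7,8,6,1,10,4L),
  c(7,10,6,0,10,7,1,10,0,7,9,0L),
  c(1,10,4,0,8,6,0,6,5,5,6,7L),
  c(6,1,10,5,1,6,7,5,6L),
  c(6,7,8,8,7,9,1,5,11L),
  c(11,1,5,9,0,4,9,4,7,7,4,6L),
  c(0,8,1,1,8,7,7,8,6,1,7,11L),
  c(4,11,1,7,11,4,6,7,4L),
  c(10,4,11,11,4,5,8,6,7,8,7,9L),
  c(0,11,10,5,11,0,0,10,6,7,9,0,0,6,7L),
  c(0,6,7,8,6,0,0,7,11,10,4,0,0,11,10L),
  c(11,6,7,11,10,6L),
  c(3,6,10L),
  c(4,8,0,3,6,10L),
  c(3,6,10,5,0,9L),
  c(5,4,9,9,4,8,3,6,10L),
  c(6,4,3,4,1,3L),
  c(6,8,3,3,8,0,3,0,1L),
  c(6,4,3,3,4,1,9,5,0L),
  c(3,6,1,1,6,9,9,6,8,9,5,1L),
  c(10,3,6,5,11,1L),
  c(3,6,10,0,4,8,5,11,1L),
  c(9,11,0,0,11,1,6,10,3L),
  c(3,6,10,1,4,8,1,8,11,11,8,9L),
  c(11,3,5,5,3,6,5,6,4L),
  c(11,3,5,3,6,5,5,6,0,0,6,8L),
  c(4,0,6,6,0,11,11,0,9,6,11,3L),
  c(8,3,6,11,3,8,9,11,8L),
  c(3,2,10,2,8,10L),
  c(4,10,0,0,10,3,0,3,2L),
  c(3,2,10,10,2,8,5,0,9L),
  c(2,10,3,5,10,2,4,10,5,9,5,2L),
  c(8,4,2,2,4,1,2,1,3L),
  c(3,2,0,1,3,0L),
  c(0,9,5,1,2,8,3,2,1,4,1,8L),
  c(1,9,5,2,9,1,3,2,1L),
  c(8,10,2,2,10,3,5,11,1L),
  c(5,11,1,4,10,3,4,3,0,0,3,2L),
  c(0,9,1,1,9,11,2,8,10,2,10,3L),
  c(4,3,2,10,3,4,4,2,9,11,1,4,4,9,11L),
  c(5,8,4,3,8,5,2,8,3,5,11,3L),
  c(3,5,11,0,5,3,2,0,3L),
  c(4,9,11,0,9,4,4,11,3,2,8,4,4,3,2L),
  c(9,3,2,9,11,3L),
  c(3,6,10,9,2,7L),
  c(0,4,8,3,6,10,7,9,2L),
  c(0,2,5,5,2,7,10,3,6L),
  c(10,3,6,8,2,7,8,7,4,4,7,5L),
  c(1,3,4,4,3,6,9,2,7L),
  c(7,9,2,6,8,0,6,0,3,3,0,1L),
  c(0,2,7,5,0,7,4,3,6,1,3,4L),
  c(8,7,5,2,7,8,8,5,1,3,6,8,8,1,3L),
  c(9,2,7,10,3,6,1,5,11L),
  c(5,11,1,3,6,10,4,8,0,7,9,2L),
  c(3,6,10,1,2,7,0,2,1,11,1,7L),
  c(4,8,1,1,8,11,11,8,2,2,7,11,3,6,10L),
  c(9,2,7,11,3,6,11,6,5,5,6,4L),
  c(3,6,11,11,6,5,5,6,8,8,0,5,9,2,7L),
  c(11,6,4,3,6,11,11,4,0,2,7,11,11,0,2L),
  c(8,3,6,11,3,8,8,2,7,8,7,11L),
  c(3,7,10,10,7,9,10,9,8L),
  c(7,10,3,7,4,10,9,4,7,0,4,9L),
  c(10,0,8,7,0,10,5,0,7,10,3,7L),
  c(7,10,3,4,10,7,5,4,7L),
  c(8,7,9,1,7,8,3,7,1,4,1,8L),
  c(0,7,9,3,7,0,1,3,0L),
  c(8,1,3,4,1,8,8,3,7,5,0,8,8,7,5L),
  c(7,1,3,7,5,1L),
  c(1,5,11,3,7,9,3,9,10,10,9,8L),
  c(0,4,9,9,4,7,7,4,10,10,3,7,11,1,5L),
  c(7,1,0,11,1,7,7,0,8,10,3,7,7,8,10L),
  c(4,11,1,7,11,4,4,10,3,4,3,7L),
  c(3,9,8,7,9,3,3,8,4,5,11,3,3,4,5L),
  c(3,5,11,0,5,3,3,7,9,3,9,0L),
  c(0,8,4,3,7,11L),
  c(11,3,7L),
  c(7,3,11L),
  c(4,8,0,11,7,3L),
  c(11,7,3,0,9,5L),
  c(8,9,4,4,9,5,3,11,7L),
  c(1,10,4,7,3,11L),
  c(0,1,8,8,1,10,7,3,11L),
  c(10,4,1,9,5,0,7,3,11L),
  c(11,7,3,10,9,5,8,9,10,1,10,5L),
  c(3,1,7,1,5,7L),
  c(3,1,7,7,1,5,8,0,4L),
  c(9,7,0,0,7,3,0,3,1L),
  c(9,7,8,8,7,1,1,7,3,8,1,4L),
  c(3,10,7,7,10,4,7,4,5L),
  c(8,0,10,10,0,7,7,0,5,7,3,10L),
  c(3,10,7,10,4,7,7,4,9,9,4,0L),
  c(10,7,3,9,7,10,8,9,10L),
  c(6,2,8,11,7,3L),
  c(4,6,0,0,6,2,11,7,3L),
  c(8,6,2,11,7,3,5,0,9L),
  c(7,3,11,5,6,2,4,6,5,9,5,2L),
  c(2,8,6,1,10,4,11,7,3L),
  c(11,7,3,10,6,2,10,2,1,1,2,0L),
  c(2,8,6,0,9,5,1,10,4,11,7,3L),
  c(6,2,10,10,2,1,1,2,9,9,5,1,11,7,3L),
  c(5,7,1,1,7,3,8,6,2L),
  c(7,3,5,5,3,1,6,2,0,6,0,4L),
  c(2,8,6,3,0,9,1,0,3,7,3,9L),
  c(9,3,1,7,3,9,9,1,4,6,2,9,9,4,6L),
  c(6,2,8,4,7,3,5,7,4,10,4,3L),
  c(10,2,0,6,2,10,10,0,5,7,3,10,10,5,7L),
  c(10,4,3,3,4,7,7,4,0,0,9,7,2,8,6L),
  c(10,7,3,9,7,10,10,6,2,10,2,9L),
  c(2,3,9,3,11,9L),
  c(11,9,3,3,9,2,4,8,0L),
  c(11,5,3,3,5,0,3,0,2L),
  c(4,8,5,5,8,3,3,8,2,3,11,5L),
  c(2,3,9,9,3,11,4,1,10L),
  c(10,8,0,1,10,0,3,9,2,11,9,3L),
  c(1,10,4,0,3,11,2,3,0,5,0,11L),
  c(5,10,8,1,10,5,5,8,2,3,11,5,5,2,3L),
  c(5,9,1,1,9,2,1,2,3L),
  c(4,8,0,5,9,2,5,2,1,1,2,3L),
  c(0,2,3,0,3,1L),
  c(2,4,8,1,4,2,3,1,2L),
  c(3,10,2,2,10,5,5,10,4,2,5,9L),
  c(5,2,3,9,2,5,5,3,10,8,0,5,5,10,8L),
  c(0,10,4,3,10,0,2,3,0L),
  c(10,2,3,10,8,2L),
  c(6,3,8,8,3,11,8,11,9L),
  c(6,0,4,11,0,6,9,0,11,3,11,6L),
  c(5,3,11,5,6,3,0,6,5,8,6,0L),
  c(5,3,11,6,3,5,4,6,5L),
  c(10,4,1,11,8,6,9,8,11,3,11,6L),
  c(6,11,9,3,11,6,6,9,0,1,10,6,6,0,1L),
  c(8,6,0,0,6,5,5,6,3,3,11,5,1,10,4L),
  c(6,1,10,5,1,6,6,3,11,6,11,5L),
  c(1,6,3,9,6,1,8,6,9,1,5,9L),
  c(9,4,6,0,4,9,9,6,3,1,5,9,9,3,1L),
  c(3,8,6,0,8,3,1,0,3L),
  c(3,4,6,3,1,4L),
  c(3,4,5,10,4,3,3,5,9,8,6,3,3,9,8L),
  c(10,6,3,9,0,5L),
  c(0,10,4,3,10,0,0,8,6,0,6,3L),
  c(10,6,3L),
  c(7,6,11,6,10,11L),
  c(7,6,11,11,6,10,0,4,8L),
  c(10,11,6,6,11,7,0,9,5L),
  c(7,6,10,11,7,10,9,4,8,5,4,9L),
  c(1,11,4,4,11,7,4,7,6L),
  c(1,8,0,7,8,1,6,8,7,11,7,1L),
  c(5,0,9,7,4,1,6,4,7,11,7,1L),
  c(1,7,6,11,7,1,1,6,8,9,5,1,1,8,9L),
  c(10,1,6,6,1,5,6,5,7L),
  c(4,8,0,5,6,10,7,6,5,1,5,10L),
  c(6,10,7,7,10,0,0,10,1,0,9,7L),
  c(1,8,9,4,8,1,1,9,7,6,10,1,1,7,6L),
  c(7,6,4,7,4,5L),
  c(5,8,0,6,8,5,7,6,5L),
  c(7,0,9,4,0,7,6,4,7L),
  c(7,8,9,7,6,8L),
  c(7,2,11,11,2,8,11,8,10L),
  c(0,7,2,10,7,0,11,7,10,0,4,10L),
  c(5,0,9,7,2,8,7,8,11,11,8,10L),
  c(2,5,4,9,5,2,2,4,10,11,7,2,2,10,11L),
  c(11,4,1,11,8,4,7,8,11,2,8,7L),
  c(2,11,7,1,11,2,0,1,2L),
  c(2,8,7,7,8,11,11,8,4,4,1,11,5,0,9L),
  c(2,11,7,1,11,2,2,9,5,2,5,1L),
  c(7,2,5,5,2,10,10,2,8,5,10,1L),
  c(10,5,7,1,5,10,10,7,2,0,4,10,10,2,0L),
  c(7,8,10,2,8,7,7,10,1,0,9,7,7,1,0L),
  c(7,2,9,4,10,1L),
  c(4,2,8,7,2,4,5,7,4L),
  c(5,2,0,5,7,2L),
  c(7,0,9,4,0,7,7,2,8,7,8,4L),
  c(7,2,9L),
  c(2,6,9,9,6,10,9,10,11L),
  c(0,4,8,2,6,10,2,10,9,9,10,11L),
  c(11,6,10,0,6,11,2,6,0,5,0,11L),
  c(2,10,11,6,10,2,2,11,5,4,8,2,2,5,4L),
  c(9,2,11,11,2,4,4,2,6,4,1,11L),
  c(6,0,1,8,0,6,6,1,11,9,2,6,6,11,9L),
  c(11,0,2,5,0,11,11,2,6,4,1,11,11,6,4L),
  c(6,8,2,5,1,11L),
  c(5,9,1,9,2,1,1,2,10,10,2,6L),
  c(9,2,5,5,2,1,1,2,6,6,10,1,4,8,0L),
  c(1,6,10,2,6,1,0,2,1L),
  c(2,4,8,1,4,2,2,6,10,2,10,1L),
  c(6,9,2,5,9,6,4,5,6L),
  c(6,9,2,5,9,6,6,8,0,6,0,5L),
  c(0,6,4,0,2,6L),
  c(6,8,2L),
  c(9,8,10,11,9,10L),
  c(10,0,4,9,0,10,11,9,10L),
  c(8,5,0,11,5,8,10,11,8L),
  c(10,5,4,10,11,5L),
  c(11,4,1,8,4,11,9,8,11L),
  c(0,11,9,0,1,11L),
  c(8,5,0,11,5,8,8,4,1,8,1,11L),
  c(11,5,1L),
  c(9,1,5,10,1,9,8,10,9L),
  c(9,1,5,10,1,9,9,0,4,9,4,10L),
  c(1,8,10,1,0,8L),
  c(1,4,10L),
  c(4,9,8,4,5,9L),
  c(5,9,0L),
  c(0,8,4L),
  integer(0)
)

.mc_edge_cornerA <- c(0,2,4,6,0,1,4,5,0,1,2,3)
.mc_edge_cornerB <- c(1,3,5,7,2,3,6,7,4,5,6,7)
.mc_edge_axis   <- c(0,0,0,0,1,1,1,1,2,2,2,2)
.mc_corner_dx <- c(0,1,0,1,0,1,0,1)
.mc_corner_dy <- c(0,0,1,1,0,0,1,1)
.mc_corner_dz <- c(0,0,0,0,1,1,1,1)
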