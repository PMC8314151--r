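# Classic 256-case marching-cubes triangulation for binary 2x2x2 voxel
# blocks, frozen here as triples of cube-edge indices (1..12). Corner c of
# a block (c = di + 2*dj + 4*dk, offsets di,dj,dk in {0,1}) sets bit c of
# the constellation code when that voxel is foreground. Triangle vertices
# sit at exact edge midpoints (binary data, isolevel 1/2); ambiguous
# (diagonal) constellations are resolved per this fixed table. A checksum
# test over all 256 per-constellation areas freezes the convention.
#
# Edge numbering (midpoint coordinates in unit-block coordinates):
#   1:(.5,0,0)  2:(.5,1,0)  3:(.5,0,1)  4:(.5,1,1)
#   5:(0,.5,0)  6:(1,.5,0)  7:(0,.5,1)  8:(1,.5,1)
#   9:(0,0,.5) 10:(1,0,.5) 11:(0,1,.5) 12:(1,1,.5)
mc_tri_table <- list(
  integer(0),
  c(5,1,9L),
  c(1,6,10L),
  c(9,5,10,10,5,6L),
  c(11,2,5L),
  c(11,2,9,9,2,1L),
  c(6,10,1,11,2,5L),
  c(6,10,2,10,11,2,10,9,11L),
  c(2,12,6L),
  c(1,9,5,12,6,2L),
  c(10,1,12,12,1,2L),
  c(2,12,5,12,9,5,12,10,9L),
  c(5,11,6,6,11,12L),
  c(1,9,6,9,12,6,9,11,12L),
  c(5,11,1,11,10,1,11,12,10L),
  c(11,10,9,11,12,10L),
  c(3,7,9L),
  c(5,1,7,7,1,3L),
  c(3,7,9,6,10,1L),
  c(3,7,10,7,6,10,7,5,6L),
  c(9,3,7,2,5,11L),
  c(11,2,7,2,3,7,2,1,3L),
  c(7,9,3,6,10,1,2,5,11L),
  c(2,6,10,2,10,3,11,2,3,7,11,3L),
  c(3,7,9,12,6,2L),
  c(3,7,1,7,5,1,12,6,2L),
  c(2,12,1,12,10,1,7,9,3L),
  c(12,10,3,5,12,3,7,5,3,12,5,2L),
  c(12,6,11,6,5,11,3,7,9L),
  c(11,12,7,12,1,7,1,3,7,12,6,1L),
  c(9,3,7,10,5,11,12,10,11,1,5,10L),
  c(10,3,7,11,10,7,12,10,11L),
  c(10,8,3L),
  c(10,8,3,5,1,9L),
  c(1,6,3,3,6,8L),
  c(9,5,3,5,8,3,5,6,8L),
  c(10,8,3,2,5,11L),
  c(11,2,9,2,1,9,8,3,10L),
  c(8,3,6,3,1,6,11,2,5L),
  c(6,8,3,11,6,3,9,11,3,2,6,11L),
  c(8,3,10,2,12,6L),
  c(5,1,9,8,3,10,12,6,2L),
  c(8,3,12,3,2,12,3,1,2L),
  c(2,12,5,5,12,9,12,8,9,8,3,9L),
  c(5,11,6,11,12,6,3,10,8L),
  c(10,8,3,12,1,9,11,12,9,6,1,12L),
  c(3,1,8,1,11,8,11,12,8,11,1,5L),
  c(12,8,3,9,12,3,11,12,9L),
  c(10,8,9,9,8,7L),
  c(10,8,1,8,5,1,8,7,5L),
  c(1,6,9,6,7,9,6,8,7L),
  c(5,8,7,6,8,5L),
  c(10,8,9,8,7,9,2,5,11L),
  c(8,7,11,1,8,11,2,1,11,8,1,10L),
  c(2,5,11,1,7,9,1,6,7,6,8,7L),
  c(7,11,2,6,7,2,8,7,6L),
  c(7,9,8,9,10,8,2,12,6L),
  c(12,6,2,10,5,1,10,8,5,8,7,5L),
  c(1,2,9,2,8,9,8,7,9,2,12,8L),
  c(5,2,12,8,5,12,7,5,8L),
  c(11,12,5,12,6,5,9,8,7,9,10,8L),
  c(1,11,12,6,1,12,1,7,11,8,1,10,1,8,7L),
  c(1,8,7,9,1,7,1,12,8,11,1,5,1,11,12L),
  c(12,8,7,12,7,11L),
  c(4,11,7L),
  c(5,1,9,4,11,7L),
  c(4,11,7,6,10,1L),
  c(6,10,5,10,9,5,4,11,7L),
  c(7,4,5,5,4,2L),
  c(7,4,9,4,1,9,4,2,1L),
  c(7,4,5,4,2,5,10,1,6L),
  c(4,2,7,2,10,7,10,9,7,10,2,6L),
  c(11,7,4,6,2,12L),
  c(4,11,7,1,9,5,6,2,12L),
  c(10,1,12,1,2,12,7,4,11L),
  c(4,11,7,2,9,5,2,12,9,12,10,9L),
  c(12,6,4,6,7,4,6,5,7L),
  c(12,6,4,4,6,7,6,1,7,1,9,7L),
  c(5,7,1,7,12,1,12,10,1,7,4,12L),
  c(9,7,4,12,9,4,10,9,12L),
  c(4,11,3,3,11,9L),
  c(5,1,11,1,4,11,1,3,4L),
  c(4,11,3,11,9,3,6,10,1L),
  c(3,4,11,6,3,11,5,6,11,10,3,6L),
  c(9,3,5,3,2,5,3,4,2L),
  c(4,1,3,2,1,4L),
  c(1,6,10,2,9,3,4,2,3,5,9,2L),
  c(2,6,10,3,2,10,4,2,3L),
  c(9,3,11,3,4,11,6,2,12L),
  c(6,2,12,5,4,11,5,1,4,1,3,4L),
  c(1,2,10,2,12,10,3,11,9,3,4,11L),
  c(5,3,4,11,5,4,5,10,3,12,5,2,5,12,10L),
  c(6,5,9,4,6,9,3,4,9,6,4,12L),
  c(4,12,6,1,4,6,3,4,1L),
  c(5,12,10,1,5,10,5,4,12,3,5,9,5,3,4L),
  c(10,3,4,10,4,12L),
  c(4,11,7,10,8,3L),
  c(1,9,5,4,11,7,8,3,10L),
  c(1,6,3,6,8,3,11,7,4L),
  c(11,7,4,9,8,3,9,5,8,5,6,8L),
  c(2,5,4,5,7,4,10,8,3L),
  c(8,3,10,7,1,9,7,4,1,4,2,1L),
  c(1,8,3,6,8,1,5,7,4,2,5,4L),
  c(9,6,8,3,9,8,9,2,6,4,9,7,9,4,2L),
  c(10,8,3,11,7,4,2,12,6L),
  c(6,2,12,4,11,7,5,1,9,8,3,10L),
  c(4,11,7,2,8,3,1,2,3,12,8,2L),
  c(5,2,9,2,12,9,12,3,9,3,12,8,4,11,7L),
  c(10,8,3,12,7,4,12,6,7,6,5,7L),
  c(4,12,7,12,6,7,6,9,7,9,6,1,10,8,3L),
  c(12,5,7,4,12,7,12,1,5,3,12,8,12,3,1L),
  c(9,7,4,12,9,4,9,8,3,9,12,8L),
  c(4,11,8,11,10,8,11,9,10L),
  c(8,4,11,8,11,5,10,8,5,1,10,5L),
  c(11,9,1,8,11,1,6,8,1,11,8,4L),
  c(8,4,11,5,8,11,6,8,5L),
  c(9,10,8,2,9,8,4,2,8,5,9,2L),
  c(1,10,8,4,1,8,2,1,4L),
  c(9,4,2,5,9,2,9,8,4,6,9,1,9,6,8L),
  c(8,4,2,8,2,6L),
  c(2,12,6,4,10,8,4,11,10,11,9,10L),
  c(1,10,5,10,8,5,8,11,5,11,8,4,12,6,2L),
  c(8,1,2,12,8,2,8,9,1,11,8,4,8,11,9L),
  c(5,2,12,8,5,12,5,4,11,5,8,4L),
  c(4,9,10,8,4,10,4,5,9,6,4,12,4,6,5L),
  c(4,12,6,1,4,6,4,10,8,4,1,10L),
  c(1,5,9,4,12,8L),
  c(12,8,4L),
  c(8,12,4L),
  c(5,1,9,12,4,8L),
  c(12,4,8,1,6,10L),
  c(9,5,10,5,6,10,4,8,12L),
  c(2,5,11,8,12,4L),
  c(1,9,2,9,11,2,8,12,4L),
  c(11,2,5,10,1,6,8,12,4L),
  c(12,4,8,11,6,10,9,11,10,2,6,11L),
  c(4,8,2,2,8,6L),
  c(4,8,2,8,6,2,9,5,1L),
  c(10,1,8,1,4,8,1,2,4L),
  c(10,9,8,9,2,8,2,4,8,9,5,2L),
  c(4,8,11,8,5,11,8,6,5L),
  c(9,11,1,11,8,1,8,6,1,8,11,4L),
  c(4,8,11,11,8,5,8,10,5,10,1,5L),
  c(11,4,8,10,11,8,9,11,10L),
  c(7,9,3,12,4,8L),
  c(5,1,7,1,3,7,12,4,8L),
  c(9,3,7,12,4,8,6,10,1L),
  c(8,12,4,6,3,7,5,6,7,10,3,6L),
  c(3,7,9,2,5,11,12,4,8L),
  c(12,4,8,11,3,7,11,2,3,2,1,3L),
  c(3,7,9,1,6,10,2,5,11,12,4,8L),
  c(7,11,3,11,2,3,2,10,3,10,2,6,12,4,8L),
  c(6,2,8,2,4,8,9,3,7L),
  c(8,6,4,6,2,4,7,1,3,7,5,1L),
  c(3,7,9,4,10,1,2,4,1,8,10,4L),
  c(10,2,4,8,10,4,10,5,2,7,10,3,10,7,5L),
  c(7,9,3,5,4,8,6,5,8,11,4,5L),
  c(11,1,3,7,11,3,11,6,1,8,11,4,11,8,6L),
  c(11,4,5,4,8,5,8,1,5,1,8,10,3,7,9L),
  c(11,4,8,10,11,8,11,3,7,11,10,3L),
  c(3,10,4,4,10,12L),
  c(12,4,10,4,3,10,5,1,9L),
  c(12,4,6,4,1,6,4,3,1L),
  c(5,6,9,6,4,9,4,3,9,4,6,12L),
  c(3,10,4,10,12,4,5,11,2L),
  c(11,1,9,2,1,11,4,3,10,12,4,10L),
  c(2,5,11,1,12,4,3,1,4,6,12,1L),
  c(6,9,11,2,6,11,6,3,9,4,6,12,6,4,3L),
  c(6,2,10,2,3,10,2,4,3L),
  c(5,1,9,6,3,10,6,2,3,2,4,3L),
  c(1,4,3,1,2,4L),
  c(3,9,5,2,3,5,4,3,2L),
  c(4,3,11,3,6,11,6,5,11,3,10,6L),
  c(6,4,3,10,6,3,6,11,4,9,6,1,6,9,11L),
  c(1,5,11,4,1,11,3,1,4L),
  c(11,4,3,11,3,9L),
  c(7,9,4,9,12,4,9,10,12L),
  c(7,5,1,12,7,1,10,12,1,4,7,12L),
  c(6,12,4,6,4,7,1,6,7,9,1,7L),
  c(6,12,4,7,6,4,5,6,7L),
  c(11,2,5,12,7,9,10,12,9,4,7,12L),
  c(7,10,12,4,7,12,7,1,10,2,7,11,7,2,1L),
  c(9,1,7,1,6,7,6,4,7,4,6,12,2,5,11L),
  c(7,11,2,6,7,2,7,12,4,7,6,12L),
  c(2,4,7,10,2,7,9,10,7,2,10,6L),
  c(10,7,5,1,10,5,10,4,7,2,10,6,10,2,4L),
  c(4,7,9,1,4,9,2,4,1L),
  c(4,7,5,4,5,2L),
  c(4,6,5,11,4,5,4,10,6,9,4,7,4,9,10L),
  c(11,4,7,10,6,1L),
  c(1,5,11,4,1,11,1,7,9,1,4,7L),
  c(11,4,7L),
  c(8,12,7,7,12,11L),
  c(8,12,7,12,11,7,1,9,5L),
  c(11,7,12,7,8,12,1,6,10L),
  c(8,11,7,12,11,8,10,9,5,6,10,5L),
  c(2,5,12,5,8,12,5,7,8L),
  c(2,1,9,8,2,9,7,8,9,12,2,8L),
  c(6,10,1,8,2,5,7,8,5,12,2,8L),
  c(2,7,8,12,2,8,2,9,7,10,2,6,2,10,9L),
  c(11,7,2,7,6,2,7,8,6L),
  c(5,1,9,6,11,7,8,6,7,2,11,6L),
  c(7,8,11,8,1,11,1,2,11,1,8,10L),
  c(2,10,9,5,2,9,2,8,10,7,2,11,2,7,8L),
  c(8,5,7,8,6,5L),
  c(6,1,9,7,6,9,8,6,7L),
  c(8,10,1,5,8,1,7,8,5L),
  c(8,10,9,8,9,7L),
  c(8,12,3,12,9,3,12,11,9L),
  c(1,3,8,11,1,8,12,11,8,1,11,5L),
  c(6,10,1,8,9,3,8,12,9,12,11,9L),
  c(3,5,6,10,3,6,3,11,5,12,3,8,3,12,11L),
  c(12,2,5,12,5,9,8,12,9,3,8,9L),
  c(3,8,12,2,3,12,1,3,2L),
  c(3,8,9,8,12,9,12,5,9,5,12,2,6,10,1L),
  c(3,8,12,2,3,12,3,6,10,3,2,6L),
  c(8,6,3,6,11,3,11,9,3,6,2,11L),
  c(11,8,6,2,11,6,11,3,8,1,11,5,11,1,3L),
  c(8,11,9,3,8,9,8,2,11,1,8,10,8,1,2L),
  c(8,10,3,5,2,11L),
  c(5,9,3,8,5,3,6,5,8L),
  c(6,1,3,6,3,8L),
  c(8,10,1,5,8,1,8,9,3,8,5,9L),
  c(8,10,3L),
  c(3,10,7,10,11,7,10,12,11L),
  c(1,9,5,3,11,7,3,10,11,10,12,11L),
  c(12,11,7,1,12,7,3,1,7,6,12,1L),
  c(3,12,11,7,3,11,3,6,12,5,3,9,3,5,6L),
  c(10,12,3,12,5,3,5,7,3,5,12,2L),
  c(7,2,1,9,7,1,7,12,2,10,7,3,7,10,12L),
  c(12,3,1,6,12,1,12,7,3,5,12,2,12,5,7L),
  c(7,3,9,6,12,2L),
  c(6,2,10,10,2,3,2,11,3,11,7,3L),
  c(10,6,3,6,2,3,2,7,3,7,2,11,5,1,9L),
  c(2,11,7,3,2,7,1,2,3L),
  c(3,9,5,2,3,5,3,11,7,3,2,11L),
  c(7,3,10,6,7,10,5,7,6L),
  c(7,3,10,6,7,10,7,1,9,7,6,1L),
  c(1,5,7,1,7,3L),
  c(7,3,9L),
  c(10,11,9,12,11,10L),
  c(11,5,1,10,11,1,12,11,10L),
  c(9,1,6,12,9,6,11,9,12L),
  c(11,5,6,11,6,12L),
  c(12,2,5,9,12,5,10,12,9L),
  c(1,10,12,1,12,2L),
  c(9,1,6,12,9,6,9,2,5,9,12,2L),
  c(12,2,6L),
  c(10,6,2,11,10,2,9,10,11L),
  c(10,6,2,11,10,2,10,5,1,10,11,5L),
  c(2,11,9,2,9,1L),
  c(2,11,5L),
  c(5,9,10,5,10,6L),
  c(6,1,10L),
  c(1,5,9L),
  integer(0)
)

# midpoint coordinates of the 12 block edges, rows indexed by edge number
mc_edge_midpoints <- matrix(c(
  0.5, 0, 0,   0.5, 1, 0,   0.5, 0, 1,   0.5, 1, 1,
  0,   0.5, 0, 1,   0.5, 0, 0,   0.5, 1, 1,   0.5, 1,
  0,   0, 0.5, 1,   0, 0.5, 0,   1, 0.5, 1,   1, 0.5),
  nrow = 12, ncol = 3, byrow = TRUE)
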