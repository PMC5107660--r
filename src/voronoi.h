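#ifndef RECELL_VORONOI_H
#define RECELL_VORONOI_H

#include <vector>

// Areas of the Voronoi tiles of (x, y) clipped to the rectangle
// bounds = {xmin, xmax, ymin, ymax}. One area per site, in input order.
std::vector<double> voronoi_areas_core(const std::vector<double> &x,
                                       const std::vector<double> &y,
                                       const double bounds[4]);

#endif
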