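// 6-node linear isoparametric wedge (pentahedral) element kernels.
//
// Node order per element: A1 A2 A3 B1 B2 B3 where the A triangle lies on
// one surface of the canvas and B on the other.  Quadrature is 3-point
// in-plane x 2-point (Gauss) through the thickness; the through-thickness
// Gauss levels carry the two specified-growth layers.
//
// Voigt order throughout: xx, yy, zz, yz, xz, xy with engineering shear.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double IP[3][2] = {{1.0/6, 1.0/6}, {2.0/3, 1.0/6}, {1.0/6, 2.0/3}};
static const double IPW = 1.0/6;
static const double ZG = 0.5773502691896257;   // 1/sqrt(3)

// shape function values and parametric derivatives at (xi, eta, zeta)
static void shape(double xi, double eta, double zeta,
                  double N[6], double dN[3][6]) {
  double L[3] = {1 - xi - eta, xi, eta};
  double dLdxi[3] = {-1, 1, 0};
  double dLdeta[3] = {-1, 0, 1};
  double lo = 0.5 * (1 - zeta), hi = 0.5 * (1 + zeta);
  for (int i = 0; i < 3; i++) {
    N[i] = L[i] * lo;        N[i + 3] = L[i] * hi;
    dN[0][i] = dLdxi[i] * lo;  dN[0][i + 3] = dLdxi[i] * hi;
    dN[1][i] = dLdeta[i] * lo; dN[1][i + 3] = dLdeta[i] * hi;
    dN[2][i] = -0.5 * L[i];    dN[2][i + 3] = 0.5 * L[i];
  }
}

// jacobian J[r][c] = dx_c/dxi_r, its determinant, and dN/dx (3 x 6)
static double jacobian(const double x[6][3], const double dN[3][6],
                       double dNdx[3][6]) {
  double J[3][3];
  for (int r = 0; r < 3; r++)
    for (int c = 0; c < 3; c++) {
      double s = 0;
      for (int n = 0; n < 6; n++) s += dN[r][n] * x[n][c];
      J[r][c] = s;
    }
  double det = J[0][0]*(J[1][1]*J[2][2]-J[1][2]*J[2][1])
             - J[0][1]*(J[1][0]*J[2][2]-J[1][2]*J[2][0])
             + J[0][2]*(J[1][0]*J[2][1]-J[1][1]*J[2][0]);
  if (det == 0.0) return det;
  double inv[3][3];   // inv[r][c] = (J^-1)[r][c]; dxi_r/dx_c = inv[c][r]
  inv[0][0] =  (J[1][1]*J[2][2]-J[1][2]*J[2][1])/det;
  inv[0][1] = -(J[0][1]*J[2][2]-J[0][2]*J[2][1])/det;
  inv[0][2] =  (J[0][1]*J[1][2]-J[0][2]*J[1][1])/det;
  inv[1][0] = -(J[1][0]*J[2][2]-J[1][2]*J[2][0])/det;
  inv[1][1] =  (J[0][0]*J[2][2]-J[0][2]*J[2][0])/det;
  inv[1][2] = -(J[0][0]*J[1][2]-J[0][2]*J[1][0])/det;
  inv[2][0] =  (J[1][0]*J[2][1]-J[1][1]*J[2][0])/det;
  inv[2][1] = -(J[0][0]*J[2][1]-J[0][1]*J[2][0])/det;
  inv[2][2] =  (J[0][0]*J[1][1]-J[0][1]*J[1][0])/det;
  // dN/dx_c = sum_r dxi_r/dx_c * dN/dxi_r, with dxi_r/dx_c = inv[c][r]
  // (J holds dx_c/dxi_r, so the xi-by-x matrix is the transposed inverse)
  for (int c = 0; c < 3; c++)
    for (int n = 0; n < 6; n++) {
      double s = 0;
      for (int r = 0; r < 3; r++) s += inv[c][r] * dN[r][n];
      dNdx[c][n] = s;
    }
  return det;
}

// strain-displacement matrix B (6 x 18) from dN/dx
static void bmatrix(const double dNdx[3][6], double B[6][18]) {
  for (int r = 0; r < 6; r++)
    for (int c = 0; c < 18; c++) B[r][c] = 0;
  for (int n = 0; n < 6; n++) {
    int cx = 3*n, cy = 3*n+1, cz = 3*n+2;
    double dx = dNdx[0][n], dy = dNdx[1][n], dz = dNdx[2][n];
    B[0][cx] = dx;               // xx
    B[1][cy] = dy;               // yy
    B[2][cz] = dz;               // zz
    B[3][cy] = dz; B[3][cz] = dy; // yz (engineering)
    B[4][cx] = dz; B[4][cz] = dx; // xz
    B[5][cx] = dy; B[5][cy] = dx; // xy
  }
}

// Assemble element stiffness triplets and the equivalent nodal force of the
// specified strain field.  pos is (2N) x 3, wedge M x 6 (1-based rows into
// pos), C 6 x 6, epsA / epsB M x 6 engineering-Voigt specified strains at
// the two through-thickness Gauss layers' bounding surfaces (zeta = -1, +1;
// interpolated linearly in zeta).
// [[Rcpp::export]]
List wedge_assemble_cpp(NumericMatrix pos, IntegerMatrix wedge,
                        NumericMatrix C, NumericMatrix epsA,
                        NumericMatrix epsB) {
  const int m = wedge.nrow();
  const int ndof = 3 * pos.nrow();
  IntegerVector ti(m * 324), tj(m * 324);
  NumericVector tx(m * 324);
  NumericVector f(ndof), vol(m), econst(m);
  double Cd[6][6];
  for (int a = 0; a < 6; a++) for (int b = 0; b < 6; b++) Cd[a][b] = C(a, b);

  for (int e = 0; e < m; e++) {
    double x[6][3];
    int nodes[6];
    for (int n = 0; n < 6; n++) {
      nodes[n] = wedge(e, n) - 1;
      for (int c = 0; c < 3; c++) x[n][c] = pos(nodes[n], c);
    }
    double Ke[18][18] = {{0}}, fe[18] = {0};
    double v = 0, ec = 0;
    for (int gz = 0; gz < 2; gz++) {
      double zeta = gz == 0 ? -ZG : ZG;
      double wA = 0.5 * (1 - zeta), wB = 0.5 * (1 + zeta);
      for (int gp = 0; gp < 3; gp++) {
        double N[6], dN[3][6], dNdx[3][6], B[6][18];
        shape(IP[gp][0], IP[gp][1], zeta, N, dN);
        double det = jacobian(x, dN, dNdx);
        if (det <= 0) stop("inverted or degenerate wedge element %d", e + 1);
        double w = IPW * det;
        v += w;
        bmatrix(dNdx, B);
        double CB[6][18];
        for (int a = 0; a < 6; a++)
          for (int c = 0; c < 18; c++) {
            double s = 0;
            for (int b = 0; b < 6; b++) s += Cd[a][b] * B[b][c];
            CB[a][c] = s;
          }
        for (int r = 0; r < 18; r++)
          for (int c = r; c < 18; c++) {
            double s = 0;
            for (int a = 0; a < 6; a++) s += B[a][r] * CB[a][c];
            Ke[r][c] += w * s;
          }
        double eps[6], Ceps[6];
        for (int a = 0; a < 6; a++)
          eps[a] = wA * epsA(e, a) + wB * epsB(e, a);
        for (int a = 0; a < 6; a++) {
          double s = 0;
          for (int b = 0; b < 6; b++) s += Cd[a][b] * eps[b];
          Ceps[a] = s;
        }
        for (int c = 0; c < 18; c++) {
          double s = 0;
          for (int a = 0; a < 6; a++) s += B[a][c] * Ceps[a];
          fe[c] += w * s;
        }
        double q = 0;
        for (int a = 0; a < 6; a++) q += eps[a] * Ceps[a];
        ec += w * q;
      }
    }
    vol[e] = v;
    econst[e] = ec;
    int base = e * 324, k = 0;
    for (int r = 0; r < 18; r++) {
      int gr = 3 * nodes[r / 3] + (r % 3);
      f[gr] += fe[r];
      for (int c = 0; c < 18; c++) {
        double val = r <= c ? Ke[r][c] : Ke[c][r];
        ti[base + k] = gr + 1;
        tj[base + k] = 3 * nodes[c / 3] + (c % 3) + 1;
        tx[base + k] = val;
        k++;
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx,
                      _["f"] = f, _["vol"] = vol, _["econst"] = econst);
}

// Displacement gradients du_i/dx_j per element at the in-plane centroid and
// the requested zeta levels.  u has length 3 * nrow(pos).  Returns a list
// of M x 9 matrices (column-major flattening of the 3 x 3 gradient:
// column index = 3*j + i for entry du_i/dx_j, zero-based).
// [[Rcpp::export]]
List wedge_gradients_cpp(NumericMatrix pos, IntegerMatrix wedge,
                         NumericVector u, NumericVector zeta_levels) {
  const int m = wedge.nrow();
  const int nl = zeta_levels.size();
  List out(nl);
  std::vector<NumericMatrix> G;
  for (int l = 0; l < nl; l++) G.push_back(NumericMatrix(m, 9));
  for (int e = 0; e < m; e++) {
    double x[6][3], ue[6][3];
    for (int n = 0; n < 6; n++) {
      int v = wedge(e, n) - 1;
      for (int c = 0; c < 3; c++) {
        x[n][c] = pos(v, c);
        ue[n][c] = u[3 * v + c];
      }
    }
    for (int l = 0; l < nl; l++) {
      double N[6], dN[3][6], dNdx[3][6];
      shape(1.0/3, 1.0/3, zeta_levels[l], N, dN);
      double det = jacobian(x, dN, dNdx);
      if (det <= 0) stop("inverted or degenerate wedge element %d", e + 1);
      for (int i = 0; i < 3; i++)
        for (int j = 0; j < 3; j++) {
          double s = 0;
          for (int n = 0; n < 6; n++) s += ue[n][i] * dNdx[j][n];
          G[l](e, 3 * j + i) = s;
        }
    }
  }
  for (int l = 0; l < nl; l++) out[l] = G[l];
  return out;
}
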