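/* Compartmental mass-action model of transplacental IgG transport.
 *
 * State layout (deSolve compiled-model convention):
 *   for each IgG species s = 0..ns-1, 8 states at offset s*8:
 *     0 IgG_M    maternal blood (M)
 *     1 IgG_STB  free IgG in syncytiotrophoblast endosomes
 *     2 C_STB    IgG-FcRn complex in STB endosomes
 *     3 IgG_STR  free IgG in villous stroma
 *     4 IgG_EC   free IgG in fetal endothelial-cell endosomes
 *     5 C_EC_Rn  IgG-FcRn complex in EC endosomes
 *     6 C_EC_R2b IgG-FcgRIIb complex at the EC surface
 *     7 IgG_F    fetal blood (M)
 *   optionally followed by 4 vaccine-response states: Ag, S_ASC, L_ASC,
 *   IgG_PT (maternal anti-PT IgG, mg/ml).
 *
 * Units: weeks, molar, litres. Rate constants k_up/k_trans/k_deg and the
 * per-species fetal clearance are volumetric clearances (L/week): a molar
 * flux k*C leaves the source compartment and the receiver divides by its
 * own volume. Binding at the EC surface happens in reaction volume V_EC,
 * so the stromal equation carries a V_EC/V_STR factor (mole conservation).
 *
 * Free receptor is algebraic: free = total(t) - sum of bound complexes,
 * with total(t) a quadratic in gestational week (clamped at zero).
 */
#include <R.h>

#define NPARMS 80

static double parms[NPARMS];

/* global layout */
#define N_SPECIES   ((int) parms[0])
#define MATERNAL_DYN ((int) parms[1])
#define VACCINE_ON  ((int) parms[2])
#define K_UP    parms[3]
#define K_TRANS parms[4]
#define K_DEG   parms[5]
#define V_M     parms[6]
#define V_STB   parms[7]
#define V_STR   parms[8]
#define V_EC    parms[9]
#define V_F     parms[10]
/* receptor schedules: R(t) = a t^2 + b t + c  (index 11..19) */
/* vaccine (already converted to per-week): 21..27, apt factor 28 */
#define VK_ASC  parms[21]
#define VK_IGG  parms[22]
#define VRHO    parms[23]
#define VD_AG   parms[24]
#define VD_IGG  parms[25]
#define VD_S    parms[26]
#define VD_L    parms[27]
#define APT_FAC parms[28]
/* per-species block: 30 + s*6: konN, koffN, konB, koffB, delta_F, driven */
#define SP(s, k) parms[30 + (s) * 6 + (k)]

static double quad_pos(double t, int off)
{
    double v = parms[off] * t * t + parms[off + 1] * t + parms[off + 2];
    return v > 0.0 ? v : 0.0;
}

void ig_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void ig_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    int ns = N_SPECIES;
    double tt = *t;
    double sumC_STB = 0.0, sumC_Rn = 0.0, sumC_R2b = 0.0;
    double dIgGPT = 0.0, m_apt = 0.0;
    int s;

    for (s = 0; s < ns; s++) {
        sumC_STB += y[s * 8 + 2];
        sumC_Rn  += y[s * 8 + 5];
        sumC_R2b += y[s * 8 + 6];
    }

    double fSTB = quad_pos(tt, 11) - sumC_STB;
    double fR2b = quad_pos(tt, 14) - sumC_R2b;
    double fRn  = quad_pos(tt, 17) - sumC_Rn;
    if (fSTB < 0.0) fSTB = 0.0;
    if (fR2b < 0.0) fR2b = 0.0;
    if (fRn  < 0.0) fRn  = 0.0;

    if (VACCINE_ON) {
        int v0 = ns * 8;
        double Ag = y[v0], S = y[v0 + 1], L = y[v0 + 2], IgGPT = y[v0 + 3];
        ydot[v0]     = -VD_AG * Ag;
        ydot[v0 + 1] = VRHO * VK_ASC * Ag - VD_S * S;
        ydot[v0 + 2] = (1.0 - VRHO) * VK_ASC * Ag - VD_L * L;
        dIgGPT       = VK_IGG * (S + L) - VD_IGG * IgGPT;
        ydot[v0 + 3] = dIgGPT;
        m_apt        = APT_FAC * IgGPT; /* molar per sub-species */
        (void) m_apt;
    }

    for (s = 0; s < ns; s++) {
        int b = s * 8;
        double konN = SP(s, 0), koffN = SP(s, 1);
        double konB = SP(s, 2), koffB = SP(s, 3);
        double dltF = SP(s, 4);
        int driven  = (int) SP(s, 5);

        double M   = y[b],     STB = y[b + 1], C   = y[b + 2];
        double STR = y[b + 3], EC  = y[b + 4];
        double Cn  = y[b + 5], Cb  = y[b + 6], F = y[b + 7];

        ydot[b] = driven ? APT_FAC * dIgGPT
                         : (MATERNAL_DYN ? -(K_UP / V_M) * M : 0.0);

        ydot[b + 1] = (K_UP / V_STB) * M - konN * STB * fSTB + koffN * C
                      - (K_DEG / V_STB) * STB;
        ydot[b + 2] = konN * STB * fSTB - koffN * C - (K_TRANS / V_STB) * C;
        ydot[b + 3] = (K_TRANS / V_STR) * C - (K_UP / V_STR) * STR
                      - (V_EC / V_STR) * (konB * STR * fR2b - koffB * Cb);
        ydot[b + 4] = (K_UP / V_EC) * STR - konN * EC * fRn + koffN * Cn
                      - (K_DEG / V_EC) * EC;
        ydot[b + 5] = konN * EC * fRn - koffN * Cn - (K_TRANS / V_EC) * Cn;
        ydot[b + 6] = konB * STR * fR2b - koffB * Cb - (K_TRANS / V_EC) * Cb;
        ydot[b + 7] = (K_TRANS / V_F) * (Cn + Cb) - (dltF / V_F) * F;
    }

    if (ip[0] >= 3) {
        yout[0] = fSTB;
        yout[1] = fR2b;
        yout[2] = fRn;
    }
}
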