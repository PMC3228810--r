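#ifndef DFEMAP_H
#define DFEMAP_H

double log1f1(double a, double b, double z);
double log1f1m1(double c, double b, double w);
double logediff(double a, double b, double z);
double log_hotnot(double XH, double TH, double n, double T, double gamma);
double omega_gamma(double gamma);

#endif
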