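name	x	y	x3	y3	z3
Fp1	-0.195652173913043	0.782608695652174	-0.23339046088374	0.93356184353496	0.272013192812557
Fp2	0.195652173913043	0.782608695652174	0.23339046088374	0.93356184353496	0.272013192812557
F3	-0.391304347826087	0.391304347826087	-0.548838639653573	0.548838639653573	0.630517482110076
F4	0.391304347826087	0.391304347826087	0.548838639653573	0.548838639653573	0.630517482110076
C3	-0.391304347826087	2.3960480852883e-17	-0.587785252292473	3.59914663902998e-17	0.809016994374947
C4	0.391304347826087	2.3960480852883e-17	0.587785252292473	3.59914663902998e-17	0.809016994374947
P3	-0.391304347826087	-0.391304347826087	-0.548838639653573	-0.548838639653573	0.630517482110076
P4	0.391304347826087	-0.391304347826087	0.548838639653573	-0.548838639653573	0.630517482110076
O1	-0.195652173913044	-0.782608695652174	-0.23339046088374	-0.93356184353496	0.272013192812557
O2	0.195652173913044	-0.782608695652174	0.23339046088374	-0.93356184353496	0.272013192812557
F7	-0.782608695652174	0.391304347826087	-0.882156658954356	0.441078329477178	0.165074335764561
F8	0.782608695652174	0.391304347826087	0.882156658954356	0.441078329477178	0.165074335764561
T7	-0.782608695652174	4.7920961705766e-17	-0.951056516295154	5.82354159244546e-17	0.309016994374947
T8	0.782608695652174	4.7920961705766e-17	0.951056516295154	5.82354159244546e-17	0.309016994374947
P7	-0.782608695652174	-0.391304347826087	-0.882156658954356	-0.441078329477178	0.165074335764561
P8	0.782608695652174	-0.391304347826087	0.882156658954356	-0.441078329477178	0.165074335764561
Fz	0	0.391304347826087	0	0.587785252292473	0.809016994374947
Cz	0	0	0	0	1
Pz	4.7920961705766e-17	-0.391304347826087	7.19829327805997e-17	-0.587785252292473	0.809016994374947
Oz	9.5841923411532e-17	-0.782608695652174	1.16470831848909e-16	-0.951056516295154	0.309016994374947
FC1	-0.195652173913043	0.195652173913044	-0.30392536826083	0.30392536826083	0.902916796307964
FC2	0.195652173913043	0.195652173913044	0.30392536826083	0.30392536826083	0.902916796307964
CP1	-0.195652173913044	-0.195652173913043	-0.30392536826083	-0.30392536826083	0.902916796307964
CP2	0.195652173913044	-0.195652173913043	0.30392536826083	-0.30392536826083	0.902916796307964
FC5	-0.58695652173913	0.195652173913043	-0.794919567840816	0.264973189280272	0.545794915354121
FC6	0.58695652173913	0.195652173913043	0.794919567840816	0.264973189280272	0.545794915354121
CP5	-0.58695652173913	-0.195652173913044	-0.794919567840816	-0.264973189280272	0.545794915354121
CP6	0.58695652173913	-0.195652173913044	0.794919567840816	-0.264973189280272	0.545794915354121
TP9	-0.978260869565217	-0.195652173913044	-0.980106259355204	-0.196021251871041	-0.0311028806971195
TP10	0.978260869565217	-0.195652173913044	0.980106259355204	-0.196021251871041	-0.0311028806971195
F1	-0.195652173913043	0.391304347826087	-0.288950802773662	0.577901605547325	0.763241225224555
F2	0.195652173913043	0.391304347826087	0.288950802773662	0.577901605547325	0.763241225224555
C1	-0.195652173913043	1.19802404264415e-17	-0.309016994374947	1.89218336521707e-17	0.951056516295154
C2	0.195652173913043	1.19802404264415e-17	0.309016994374947	1.89218336521707e-17	0.951056516295154
P1	-0.195652173913044	-0.391304347826087	-0.288950802773662	-0.577901605547325	0.763241225224555
P2	0.195652173913044	-0.391304347826087	0.288950802773662	-0.577901605547325	0.763241225224555
AF3	-0.391304347826087	0.58695652173913	-0.502318874110221	0.753478311165332	0.424200640400363
AF4	0.391304347826087	0.58695652173913	0.502318874110221	0.753478311165332	0.424200640400363
FC3	-0.391304347826087	0.195652173913044	-0.577901605547325	0.288950802773662	0.763241225224555
FC4	0.391304347826087	0.195652173913044	0.577901605547325	0.288950802773662	0.763241225224555
CP3	-0.391304347826087	-0.195652173913043	-0.577901605547325	-0.288950802773662	0.763241225224555
CP4	0.391304347826087	-0.195652173913043	0.577901605547325	-0.288950802773662	0.763241225224555
PO3	-0.391304347826087	-0.58695652173913	-0.502318874110221	-0.753478311165332	0.424200640400363
PO4	0.391304347826087	-0.58695652173913	0.502318874110221	-0.753478311165332	0.424200640400363
F5	-0.58695652173913	0.391304347826087	-0.753478311165332	0.502318874110221	0.424200640400363
F6	0.58695652173913	0.391304347826087	0.753478311165332	0.502318874110221	0.424200640400363
C5	-0.58695652173913	3.59407212793245e-17	-0.809016994374947	4.95380036308546e-17	0.587785252292473
C6	0.58695652173913	3.59407212793245e-17	0.809016994374947	4.95380036308546e-17	0.587785252292473
P5	-0.586956521739131	-0.391304347826087	-0.753478311165332	-0.502318874110221	0.424200640400363
P6	0.586956521739131	-0.391304347826087	0.753478311165332	-0.502318874110221	0.424200640400363
AF7	-0.782608695652174	0.58695652173913	-0.8	0.6	6.12323399573677e-17
AF8	0.782608695652174	0.58695652173913	0.8	0.6	6.12323399573677e-17
FT7	-0.782608695652174	0.195652173913043	-0.93356184353496	0.23339046088374	0.272013192812557
FT8	0.782608695652174	0.195652173913043	0.93356184353496	0.23339046088374	0.272013192812557
TP7	-0.782608695652174	-0.195652173913044	-0.93356184353496	-0.23339046088374	0.272013192812557
TP8	0.782608695652174	-0.195652173913044	0.93356184353496	-0.23339046088374	0.272013192812557
PO7	-0.782608695652174	-0.58695652173913	-0.8	-0.6	6.12323399573677e-17
PO8	0.782608695652174	-0.58695652173913	0.8	-0.6	6.12323399573677e-17
Fpz	0	0.782608695652174	0	0.951056516295154	0.309016994374947
CPz	2.3960480852883e-17	-0.195652173913043	3.78436673043415e-17	-0.309016994374947	0.951056516295154
POz	7.1881442558649e-17	-0.58695652173913	9.90760072617092e-17	-0.809016994374947	0.587785252292473
AFz	0	0.58695652173913	0	0.809016994374947	0.587785252292473
FT9	-0.978260869565217	0.195652173913043	-0.980106259355204	0.196021251871041	-0.0311028806971195
FT10	0.978260869565217	0.195652173913043	0.980106259355204	0.196021251871041	-0.0311028806971195
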