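subject,group,accuracy_pct,max_force_N,max_torque_Nm
A,senior,91.67,1.79,4.13
B,senior,91.67,2.53,7.03
C,senior,91.67,1.90,5.55
D,senior,87.50,8.84,10.05
I,senior,91.67,1.05,2.14
K,senior,91.67,3.58,7.45
L,senior,83.33,2.12,6.91
M,senior,91.67,3.00,6.45
N,senior,87.50,0.97,1.92
O,senior,91.67,7.01,8.75
P,senior,91.67,1.67,3.58
Q,senior,95.83,2.84,7.10
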