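# seed=20
# note=synthetic dataset generated by simulate_mixture_dataset() at force ratio 3.3
k	velocity_um_s	uncertainty_um_s	uncertainty_kind	n
0	1.75653602746634	0.103886777234495	sd	3
0.2	1.96902622458752	0.0956380499730068	sd	3
0.4	2.32716346495971	0.162746011108298	sd	3
0.6	3.24302431553387	0.0458301641336789	sd	3
0.8	4.46673844543842	0.329428345387607	sd	3
1	6.63147027288471	0.235641706454327	sd	3
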