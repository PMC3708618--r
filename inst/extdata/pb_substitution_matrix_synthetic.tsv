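letter	a	b	c	d	e	f	g	h	i	j	k	l	m	n	o	p
a	2	-2.0773	-1.2068	-1.667	-2.5791	-2.2665	-1.8516	-2.9209	-2.5367	-2.725	-3.0029	-2.366	-2.6259	-3.0354	-2.5664	-2.1218
b	-2.0773	2	-1.1034	-0.6165	-1.7971	-1.8111	-2.1528	-2.0683	-0.8216	-2.0562	-0.9453	-1.7996	-2.5645	-3.0329	-2.5406	-1.8024
c	-1.2068	-1.1034	2	-0.4941	-1.6914	-1.3434	-1.2515	-2.1771	-2.1417	-2.0116	-2.3085	-2.8536	-2.5703	-2.9575	-2.3439	-1.5076
d	-1.667	-0.6165	-0.4941	2	-0.8685	-0.726	-2.2033	-1.6328	-1.4573	-1.3997	-1.9145	-2.6828	-3.7211	-4.0173	-3.3928	-2.7565
e	-2.5791	-1.7971	-1.6914	-0.8685	2	-1.5826	-1.1	-2.2283	-2.4466	-2.1987	-2.282	-3.0187	-3.9245	-3.0906	-3.9289	-3.3319
f	-2.2665	-1.8111	-1.3434	-0.726	-1.5826	2	-2.7027	-0.4556	-2.4165	-1.1461	-0.7597	-1.7967	-2.6748	-3.2848	-2.8946	-3.0234
g	-1.8516	-2.1528	-1.2515	-2.2033	-1.1	-2.7027	2	-3.0537	-2.9781	-3.326	-2.9014	-2.525	-2.2477	-0.983	-2.2749	-1.9405
h	-2.9209	-2.0683	-2.1771	-1.6328	-2.2283	-0.4556	-3.0537	2	-2.6534	-1.7657	-1.3612	-2.2911	-3.056	-3.7191	-2.112	-3.2867
i	-2.5367	-0.8216	-2.1417	-1.4573	-2.4466	-2.4165	-2.9781	-2.6534	2	-1.3162	-1.5636	-2.2783	-3.2398	-3.5923	-3.5232	-1.1605
j	-2.725	-2.0562	-2.0116	-1.3997	-2.1987	-1.1461	-3.326	-1.7657	-1.3162	2	-1.0864	-2.108	-2.7252	-3.3129	-3.64	-2.3674
k	-3.0029	-0.9453	-2.3085	-1.9145	-2.282	-0.7597	-2.9014	-1.3612	-1.5636	-1.0864	2	-0.8166	-1.7925	-2.4612	-2.5342	-2.5282
l	-2.366	-1.7996	-2.8536	-2.6828	-3.0187	-1.7967	-2.525	-2.2911	-2.2783	-2.108	-0.8166	2	-0.8355	-1.6375	-1.8062	-2.258
m	-2.6259	-2.5645	-2.5703	-3.7211	-3.9245	-2.6748	-2.2477	-3.056	-3.2398	-2.7252	-1.7925	-0.8355	2	-0.4215	-0.6598	-1.5832
n	-3.0354	-3.0329	-2.9575	-4.0173	-3.0906	-3.2848	-0.983	-3.7191	-3.5923	-3.3129	-2.4612	-1.6375	-0.4215	2	-1.8496	-2.1014
o	-2.5664	-2.5406	-2.3439	-3.3928	-3.9289	-2.8946	-2.2749	-2.112	-3.5232	-3.64	-2.5342	-1.8062	-0.6598	-1.8496	2	-1.9745
p	-2.1218	-1.8024	-1.5076	-2.7565	-3.3319	-3.0234	-1.9405	-3.2867	-1.1605	-2.3674	-2.5282	-2.258	-1.5832	-2.1014	-1.9745	2
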