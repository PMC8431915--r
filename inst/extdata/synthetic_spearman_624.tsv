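item	IU1	IU2	IU3	IU4	IU5	IU6	IU7	IU8	IU9	IU10	IU11	IU12	A1	A2	A3	A4	A5	A6	A7
IU1	1	0.685586064779954	0.745759364479442	0.715572253658289	0.466149559700737	0.763787763259852	0.752400657191344	0.73567936369084	0.724645198200464	0.546135363502486	0.752699365502004	0.732847384690475	0.707910177190146	0.702314693599371	0.717425379384287	0.689088629190519	0.694779693493761	0.646655050096095	0.657354864330706
IU2	0.685586064779954	1	0.716115493052421	0.689255786648736	0.497436622649712	0.755380306450413	0.716913488224153	0.707214598084146	0.734110013704614	0.556861526331053	0.756929095851681	0.678293890082066	0.662681099850359	0.695856102063222	0.712818509166384	0.722312555163567	0.682873309507399	0.695583861729963	0.674498769215923
IU3	0.745759364479442	0.716115493052421	1	0.765954165606623	0.468123043022928	0.80640245457362	0.820815968302044	0.781657496406577	0.807517641645793	0.605832652129355	0.778210630616254	0.847539533060467	0.628756075137327	0.719726090536292	0.789573820169664	0.740130219689425	0.806308627860927	0.688117789204692	0.816462416541758
IU4	0.715572253658289	0.689255786648736	0.765954165606623	1	0.433087383527689	0.768380884137998	0.752178961523818	0.723216324807867	0.76127020796828	0.549418732214845	0.753772584424448	0.694910369494765	0.641090797784886	0.704979208523111	0.722579904705902	0.701112241555178	0.714629409127266	0.625508338985466	0.675184781955366
IU5	0.466149559700737	0.497436622649712	0.468123043022928	0.433087383527689	1	0.484783338894244	0.452533859315533	0.475734812558251	0.464620603577116	0.368599790034752	0.473032103912964	0.408509512965375	0.432049012340271	0.415648028196108	0.44747691795608	0.391976046629211	0.414141870652152	0.381032335657767	0.393481567500817
IU6	0.763787763259852	0.755380306450413	0.80640245457362	0.768380884137998	0.484783338894244	1	0.77371475961664	0.8057858622536	0.82293254444129	0.610505845822525	0.802131419742918	0.753937388242142	0.700148063772595	0.733896238020314	0.774907601862949	0.705163592197357	0.737507164922759	0.713153393222083	0.746791269664719
IU7	0.752400657191344	0.716913488224153	0.820815968302044	0.752178961523818	0.452533859315533	0.77371475961664	1	0.792150175070714	0.787931779165797	0.592859186722144	0.806783691373962	0.821652076226673	0.662131827704049	0.682092797048533	0.755273836875219	0.743890654471093	0.788836503624141	0.676292537061913	0.750475957936161
IU8	0.73567936369084	0.707214598084146	0.781657496406577	0.723216324807867	0.475734812558251	0.8057858622536	0.792150175070714	1	0.771034246276517	0.592920602120414	0.82747669236955	0.769489747149222	0.715906062594654	0.719348822275499	0.768053659599371	0.706067445035248	0.75612510582435	0.672991773555198	0.711928199785813
IU9	0.724645198200464	0.734110013704614	0.807517641645793	0.76127020796828	0.464620603577116	0.82293254444129	0.787931779165797	0.771034246276517	1	0.61921672247393	0.792569664003946	0.753185652091513	0.679088060950407	0.727459774145192	0.797754959524819	0.723263115086513	0.746614463824663	0.702577633000593	0.731474150026322
IU10	0.546135363502486	0.556861526331053	0.605832652129355	0.549418732214845	0.368599790034752	0.610505845822525	0.592859186722144	0.592920602120414	0.61921672247393	1	0.611555676817263	0.576926074364561	0.558261176567069	0.543364066231202	0.600943723758098	0.547450630094103	0.568445625883568	0.590284984768501	0.583901276085372
IU11	0.752699365502004	0.756929095851681	0.778210630616254	0.753772584424448	0.473032103912964	0.802131419742918	0.806783691373962	0.82747669236955	0.792569664003946	0.611555676817263	1	0.754862435059641	0.779949856449461	0.743950088511936	0.807092358834935	0.75834801557837	0.762675367761581	0.726515951220181	0.717257249019766
IU12	0.732847384690475	0.678293890082066	0.847539533060467	0.694910369494765	0.408509512965375	0.753937388242142	0.821652076226673	0.769489747149222	0.753185652091513	0.576926074364561	0.754862435059641	1	0.635900569375174	0.663422244872181	0.751765466774337	0.728745289392895	0.796133763716532	0.65244510211406	0.760723214642069
A1	0.707910177190146	0.662681099850359	0.628756075137327	0.641090797784886	0.432049012340271	0.700148063772595	0.662131827704049	0.715906062594654	0.679088060950407	0.558261176567069	0.779949856449461	0.635900569375174	1	0.674314020975324	0.682533207088972	0.623418853801157	0.595009006062183	0.70446152159927	0.575661041542938
A2	0.702314693599371	0.695856102063222	0.719726090536292	0.704979208523111	0.415648028196108	0.733896238020314	0.682092797048533	0.719348822275499	0.727459774145192	0.543364066231202	0.743950088511936	0.663422244872181	0.674314020975324	1	0.708984078216546	0.718053581992646	0.686254115255233	0.703082330084825	0.661337723858927
A3	0.717425379384287	0.712818509166384	0.789573820169664	0.722579904705902	0.44747691795608	0.774907601862949	0.755273836875219	0.768053659599371	0.797754959524819	0.600943723758098	0.807092358834935	0.751765466774337	0.682533207088972	0.708984078216546	1	0.756290865679145	0.754485362140304	0.724031686891939	0.74368152441877
A4	0.689088629190519	0.722312555163567	0.740130219689425	0.701112241555178	0.391976046629211	0.705163592197357	0.743890654471093	0.706067445035248	0.723263115086513	0.547450630094103	0.75834801557837	0.728745289392895	0.623418853801157	0.718053581992646	0.756290865679145	1	0.759384580370436	0.694088506047705	0.719326772426762
A5	0.694779693493761	0.682873309507399	0.806308627860927	0.714629409127266	0.414141870652152	0.737507164922759	0.788836503624141	0.75612510582435	0.746614463824663	0.568445625883568	0.762675367761581	0.796133763716532	0.595009006062183	0.686254115255233	0.754485362140304	0.759384580370436	1	0.667640875256432	0.792771717486908
A6	0.646655050096095	0.695583861729963	0.688117789204692	0.625508338985466	0.381032335657767	0.713153393222083	0.676292537061913	0.672991773555198	0.702577633000593	0.590284984768501	0.726515951220181	0.65244510211406	0.70446152159927	0.703082330084825	0.724031686891939	0.694088506047705	0.667640875256432	1	0.645988346170156
A7	0.657354864330706	0.674498769215923	0.816462416541758	0.675184781955366	0.393481567500817	0.746791269664719	0.750475957936161	0.711928199785813	0.731474150026322	0.583901276085372	0.717257249019766	0.760723214642069	0.575661041542938	0.661337723858927	0.74368152441877	0.719326772426762	0.792771717486908	0.645988346170156	1
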