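id,category,text
G01,activity,Walk for 30 minutes today.
G02,activity,Take the stairs instead of the elevator.
G03,activity,Stretch for 10 minutes after waking up.
G04,activity,Go for a 15-minute walk after lunch.
G05,activity,Do 20 squats during a work break.
G06,activity,Ride a bicycle for 20 minutes.
G07,activity,Park farther away and walk the difference.
G08,activity,Do a 10-minute core workout.
G09,activity,Get off the bus one stop early and walk.
G10,activity,Jog lightly for 15 minutes.
G11,activity,Do 15 push-ups in the morning.
G12,activity,Take a brisk evening walk around your block.
G13,activity,Stand up and move for 5 minutes every hour.
G14,activity,Try a 20-minute online exercise class.
G15,activity,Do jumping jacks for 5 minutes.
G16,activity,Walk while taking phone calls.
G17,activity,Swim for 30 minutes this week.
G18,activity,Do 3 sets of lunges today.
G19,activity,Play an active game or sport with a friend.
G20,activity,Dance to three songs in a row.
G21,activity,Take a 20-minute walk before breakfast.
G22,food,Eat fish for dinner.
G23,food,Add a serving of vegetables to lunch.
G24,food,Swap soda for sparkling water.
G25,food,Eat a piece of fruit instead of a pastry.
G26,food,Choose whole-grain bread.
G27,food,Have a salad as a side instead of fries.
G28,food,Skip dessert after dinner tonight.
G29,food,Drink a glass of water before every meal.
G30,food,Use a smaller plate at dinner.
G31,food,Snack on nuts instead of chips.
G32,food,Add beans or lentils to one meal.
G33,food,Cook at home instead of ordering out.
G34,food,Choose grilled over fried options.
G35,food,Have oatmeal for breakfast.
G36,food,Limit yourself to one coffee with sugar.
G37,food,Eat slowly and stop when comfortably full.
G38,food,Replace cheese with avocado in a sandwich.
G39,food,Have a vegetarian dinner tonight.
G40,food,Keep cut vegetables ready for snacking.
G41,food,Choose low-fat dairy today.
G42,food,Avoid second helpings at dinner.
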